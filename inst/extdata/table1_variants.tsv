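subject	group	c_pos	ref	alt	printed_p
PPMS-1	PPMS	793	A	G	N265D
PPMS-1	PPMS	823	C	T	P275S
PPMS-1	PPMS	950	G	A	G317D
PPMS-2	PPMS	831	G	T	K277N
PPMS-3	PPMS	793	A	G	N265D
PPMS-3	PPMS	850	A	G	R284G
PPMS-4	PPMS	817	T	C	F273L
PPMS-4	PPMS	841	T	C	F281L
PPMS-4	PPMS	853	A	G	S285G
PPMS-4	PPMS	901	A	G	N301D
PPMS-4	PPMS	922	T	G	S308P
SPMS-1	SPMS	787	T	C	F263L
SPMS-1	SPMS	896	C	T	P299L
SPMS-1	SPMS	898	C	T	R300S
SPMS-1	SPMS	941	A	G	Y314C
SPMS-1	SPMS	958	T	C	F320L
SPMS-3	SPMS	817	T	G	F273L
SPMS-4	SPMS	755	G	A	S252N
SPMS-4	SPMS	884	A	G	Y295C
SPMS-4	SPMS	886	T	C	F296L
SPMS-4	SPMS	902	A	G	N301S
RRMS-1	RRMS	937	A	G	S313G
RRMS-1	RRMS	955	A	G	R319G
RRMS-2	RRMS	826	A	C	M276L
RRMS-2	RRMS	839	A	G	N280S
RRMS-2	RRMS	940	T	C	Y314H
RRMS-5	RRMS	775	A	G	S259G
HC-4	HC	922	T	C	S308P
HC-5	HC	952	A	G	R318G
HC-6	HC	949	G	A	G317S
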