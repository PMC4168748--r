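number	hgvs_name	local_id	ss_id
1	NM_002136.2:c.755G>A	NP_002127.1:c.755G>A	ss1056389899
2	NM_002136.2:c.775A>G	NP_002127.1:c.775A>G	ss1056389900
3	NM_002136.2:c.787T>C	NP_002127.1:c.787T>C	ss1056389901
4	NM_002136.2:c.793A>G	NP_002127.1:c.793A>G	ss1056389902
5	NM_002136.2:c.826A>C	NP_002127.1:c.826A>C	ss1056389903
6	NM_002136.2:c.839A>G	NP_002127.1:c.839A>G	ss1056389904
7	NM_002136.2:c.937A>G	NP_002127.1:c.937A>G	ss1056389905
8	NM_002136.2:c.940T>C	NP_002127.1:c.940T>C	ss1056389906
9	NM_002136.2:c.955A>G	NP_002127.1:c.955A>G	ss1056389907
10	NM_002136.2:c.817T>G	NP_002127.1:c.817T>G	ss1056389908
11	NM_002136.2:c.817T>C	NP_002127.1:c.817T>C	ss1056389909
12	NM_002136.2:c.823C>T	NP_002127.1:c.823C>T	ss1056389910
13	NM_002136.2:c.831G>T	NP_002127.1:c.831G>T	ss1056389911
14	NM_002136.2:c.841T>C	NP_002127.1:c.841T>C	ss1056389912
15	NM_002136.2:c.850A>G	NP_002127.1:c.850A>G	ss1056389913
16	NM_002136.2:c.853A>G	NP_002127.1:c.853A>G	ss1056389914
17	NM_002136.2:c.884A>G	NP_002127.1:c.884A>G	ss1056389915
18	NM_002136.2:c.886T>C	NP_002127.1:c.886T>C	ss1056389916
19	NM_002136.2:c.896C>T	NP_002127.1:c.896C>T	ss1056389917
20	NM_002136.2:c.898C>T	NP_002127.1:c.898C>T	ss1056389918
21	NM_002136.2:c.902A>G	NP_002127.1:c.902A>G	ss1056389919
22	NM_002136.2:c.901A>G	NP_002127.1:c.901A>G	ss1056389920
23	NM_002136.2:c.922T>G	NP_002127.1:c.922T>G	ss1056389921
24	NM_002136.2:c.941A>G	NP_002127.1:c.941A>G	ss1056389922
25	NM_002136.2:c.950G>A	NP_002127.1:c.950G>A	ss1056389923
26	NM_002136.2:c.958T>C	NP_002127.1:c.958T>C	ss1056389924
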