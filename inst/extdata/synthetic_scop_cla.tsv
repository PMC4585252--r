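# synthetic classification
d010005	0xxx	c.81.1.1	10005	cl=10001,cf=10002,sf=10003,fa=10004,px=10005
d010006	0xxx	c.81.1.1	10006	cl=10001,cf=10002,sf=10003,fa=10004,px=10006
d010010	0xxx	c.83.1.1	10010	cl=10001,cf=10007,sf=10008,fa=10009,px=10010
d010011	0xxx	c.83.1.1	10011	cl=10001,cf=10007,sf=10008,fa=10009,px=10011
d010012	0xxx	c.83.1.1	10012	cl=10001,cf=10007,sf=10008,fa=10009,px=10012
d010017	0xxx	f.24.1.1	10017	cl=10013,cf=10014,sf=10015,fa=10016,px=10017
d010018	0xxx	f.24.1.1	10018	cl=10013,cf=10014,sf=10015,fa=10016,px=10018
d010019	0xxx	f.24.1.1	10019	cl=10013,cf=10014,sf=10015,fa=10016,px=10019
d010024	0xxx	b.6.1.3	10024	cl=10020,cf=10021,sf=10022,fa=10023,px=10024
d010025	0xxx	b.6.1.3	10025	cl=10020,cf=10021,sf=10022,fa=10023,px=10025
d010026	0xxx	b.6.1.3	10026	cl=10020,cf=10021,sf=10022,fa=10023,px=10026
d010027	0xxx	b.6.1.3	10027	cl=10020,cf=10021,sf=10022,fa=10023,px=10027
d010029	0xxx	b.6.1.2	10029	cl=10020,cf=10021,sf=10022,fa=10028,px=10029
d010030	0xxx	b.6.1.2	10030	cl=10020,cf=10021,sf=10022,fa=10028,px=10030
d010031	0xxx	b.6.1.2	10031	cl=10020,cf=10021,sf=10022,fa=10028,px=10031
d010032	0xxx	b.6.1.2	10032	cl=10020,cf=10021,sf=10022,fa=10028,px=10032
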