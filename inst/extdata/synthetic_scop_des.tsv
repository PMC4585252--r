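# synthetic descriptions
10001	cl	c	-	class c
10002	cf	c.81	-	fold c.81
10003	sf	c.81.1	-	superfamily c.81.1
10004	fa	c.81.1.1	-	aldehyde ferredoxin oxidoreductase
10005	px	c.81.1.1	d010005	aldehyde ferredoxin oxidoreductase domain 1
10006	px	c.81.1.1	d010006	aldehyde ferredoxin oxidoreductase domain 2
10007	cf	c.83	-	fold c.83
10008	sf	c.83.1	-	superfamily c.83.1
10009	fa	c.83.1.1	-	aconitase iron-sulfur domain
10010	px	c.83.1.1	d010010	aconitase iron-sulfur domain domain 1
10011	px	c.83.1.1	d010011	aconitase iron-sulfur domain domain 2
10012	px	c.83.1.1	d010012	aconitase iron-sulfur domain domain 3
10013	cl	f	-	class f
10014	cf	f.24	-	fold f.24
10015	sf	f.24.1	-	superfamily f.24.1
10016	fa	f.24.1.1	-	cytochrome c oxidase subunit I-like (heme-copper oxidase)
10017	px	f.24.1.1	d010017	cytochrome c oxidase subunit I-like (heme-copper oxidase) domain 1
10018	px	f.24.1.1	d010018	cytochrome c oxidase subunit I-like (heme-copper oxidase) domain 2
10019	px	f.24.1.1	d010019	cytochrome c oxidase subunit I-like (heme-copper oxidase) domain 3
10020	cl	b	-	class b
10021	cf	b.6	-	fold b.6
10022	sf	b.6.1	-	superfamily b.6.1
10023	fa	b.6.1.3	-	multidomain cupredoxins
10024	px	b.6.1.3	d010024	copper-containing nitrite reductase NirK
10025	px	b.6.1.3	d010025	multicopper oxidase CueO
10026	px	b.6.1.3	d010026	copper-containing nitrite reductase, NirK-type
10027	px	b.6.1.3	d010027	blue multidomain copper protein of unknown function
10028	fa	b.6.1.2	-	plastocyanin/azurin-like
10029	px	b.6.1.2	d010029	plastocyanin/azurin-like domain 1
10030	px	b.6.1.2	d010030	plastocyanin/azurin-like domain 2
10031	px	b.6.1.2	d010031	plastocyanin/azurin-like domain 3
10032	px	b.6.1.2	d010032	plastocyanin/azurin-like domain 4
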