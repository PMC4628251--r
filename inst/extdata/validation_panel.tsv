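ecr	species	assembly	region	status
1	zf	danRer7	chr6:20797116-20798106	positive
1	mm	mm9	chr5:107545775-107546750	negative
2	zf	danRer7	chr6:43538446-43539094	positive
2	mm	mm9	chr6:98881656-98882625	negative
2	mm	mm9	chr6:98883956-98884889	negative
3	zf	danRer7	chr9:11657708-11658704	positive
3	mm	mm9	.	not_tested
4	zf	danRer7	chr19:22713465-22714026	positive
4	mm	mm9	chr18:80876694-80877675	negative
4	mm	mm9	chr18:80876778-80877739	negative
5	zf	danRer7	chr19:41272614-41273241	positive
5	mm	mm9	.	not_tested
6	zf	danRer7	chr2:39790777-39791782	positive
6	mm	mm9	chr1:77387974-77389004	positive
7	zf	danRer7	chr2:39792312-39793241	positive
7	mm	mm9	chr1:77390034-77391031	positive
8	zf	danRer7	chr2:39837096-39838009	positive
8	mm	mm9	chr1:77503689-77504676	negative
8	mm	mm9	chr1:77506344-77507445	negative
9	zf	danRer7	chr4:16470975-16471819	positive
9	mm	mm9	chr10:87004979-87005964	positive
9	mm	mm9	chr10:87008830-87009792	positive
10	zf	danRer7	chr9:22365926-22366799	positive
10	mm	mm9	chr14:58234894-58235874	positive
11	zf	danRer7	chr9:22368460-22369405	positive
11	mm	mm9	chr14:58234894-58235874	positive
12	zf	danRer7	chr14:41645428-41646386	positive
12	mm	mm9	chrX:130162955-130163923	positive
13	zf	danRer7	chr20:21970078-21970911	positive
13	mm	mm9	chr12:72999373-73000279	positive
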