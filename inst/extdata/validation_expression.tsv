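ecr	species	tissue	time
1	zf	Spinal cord	48
2	zf	Epidermis	24
2	zf	Epidermis	48
3	zf	Tail bud	24
3	zf	Eye	48
3	zf	Heart	48
4	zf	Notochord	24
4	zf	Notochord	48
5	zf	Epidermis	24
5	zf	Epidermis	48
6	zf	Epidermis	24
6	zf	Epidermis	48
6	zf	Otic vesicle	24
6	zf	Otic vesicle	48
6	zf	Somitic muscle	24
6	zf	Somitic muscle	48
6	mm	Epidermis	24
6	mm	Epidermis	48
6	mm	Notochord	24
6	mm	Olfactory epithelium	24
6	mm	Olfactory epithelium	48
6	mm	Spinal cord	24
6	mm	Otic vesicle	48
6	mm	Pectoral fin	48
7	zf	Hindbrain	24
7	zf	Hindbrain	48
7	zf	Olfactory epithelium	24
7	zf	Olfactory epithelium	48
7	mm	Eye	24
7	mm	Eye	48
7	mm	Olfactory bulb	24
7	mm	Olfactory bulb	48
7	mm	Hindbrain	24
7	mm	Hindbrain	48
8	zf	Somitic muscle	24
8	zf	Somitic muscle	48
8	zf	Olfactory epithelium	48
8	zf	Hindbrain	48
9	zf	Spinal cord	24
9	zf	Spinal cord	48
9	mm	Midbrain	24
9	mm	Yolk	24
9	mm	Somitic muscle	24
9	mm	Somitic muscle	48
9	mm	Skin under yolk	24
9	mm	Skin under yolk	48
9	mm	Pharyngeal arches	48
9	mm	Pectoral fin	48
10	zf	Somitic muscle	24
10	zf	Somitic muscle	48
10	zf	Olfactory epithelium	48
10	mm	Somitic muscle	24
10	mm	Somitic muscle	48
10	mm	Pericardium	24
10	mm	Pericardium	48
11	zf	Hindbrain	24
11	zf	Somitic muscle	24
11	zf	Somitic muscle	48
11	zf	Heart	48
11	mm	Somitic muscle	24
11	mm	Somitic muscle	48
11	mm	Pericardium	24
11	mm	Pericardium	48
12	zf	Epidermis	24
12	zf	Epidermis	48
12	zf	Otic vesicle	24
12	zf	Otic vesicle	48
12	zf	Yolk	24
12	zf	Yolk	48
12	mm	Epidermis	24
12	mm	Olfactory epithelium	24
13	zf	Hindbrain	24
13	zf	Olfactory epithelium	24
13	zf	Olfactory epithelium	48
13	zf	Line under eye	24
13	zf	Line under eye	48
13	zf	Spinal cord	48
13	mm	Spinal cord	24
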