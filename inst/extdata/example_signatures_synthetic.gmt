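blood	synthetic example signature	G00001	G00003	G00004	G00005	G00007	G00002	G00008	G00006
brain	synthetic example signature	G00016	G00009	G00011	G00014	G00013	G00010	G00012	G00015
heart	synthetic example signature	G00024	G00020	G00017	G00018	G00022	G00021	G00019	G00023
kidney	synthetic example signature	G00026	G00030	G00027	G00029	G00028	G00025	G00032	G00031
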