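complement_toy	complement_toy synthetic toy set	P00001	P00002	P00003	P00004	P00005	P00006	P00007	P00008
coagulation_toy	coagulation_toy synthetic toy set	P00009	P00010	P00011	P00012	P00013	P00014
oxphos_toy	oxphos_toy synthetic toy set	P00015	P00016	P00017	P00018	P00019	P00020	P00021	P00022
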