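sample	group
COAD_01	COAD
COAD_02	COAD
COAD_03	COAD
COAD_04	COAD
READ_01	READ
READ_02	READ
READ_03	READ
READ_04	READ
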