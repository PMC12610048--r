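name	forward	reverse	size	tm
Mar28	AGTGATTCAGATTGGATGGACTGA	AACACTATATCCTGCACCGGATT	509	56
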