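label	x	y	z
CH01	-57	24	38
CH02	-45	24	38
CH03	-33	24	38
CH04	-21	24	38
CH05	-57	42	38
CH06	-45	42	38
CH07	-33	42	38
CH08	-21	42	38
CH09	-57	60	38
CH10	-45	60	38
CH11	-33	60	38
CH12	-21	60	38
CH13	21	24	38
CH14	33	24	38
CH15	45	24	38
CH16	57	24	38
CH17	21	42	38
CH18	33	42	38
CH19	45	42	38
CH20	57	42	38
CH21	21	60	38
CH22	33	60	38
CH23	45	60	38
CH24	57	60	38
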