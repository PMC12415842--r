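domain	first	last
LC	1	163
RGG1	164	284
RRM	285	371
RGG2	372	422
ZnF	423	453
RGG3	453	507
NLS	508	526
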