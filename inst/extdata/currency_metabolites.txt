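C00001
C00002
C00003
C00004
C00005
C00006
C00008
C00009
C00010
C00011
C00013
C00080
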