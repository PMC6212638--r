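# Curated, partial list of human dicarboxylate-clamp TPR proteins used by
# the example network. One id per line.
FKBP51
AIP
Tom70
SGTA
DNAJC7
FKBP52
FKBP36
FKBP38
FKBPL
CHIP
UNC45A
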