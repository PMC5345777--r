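variant_type	svc_count
deletion	1194270
copy number loss	633268
mobile element insertion	517506
duplication	303790
insertion	232552
indel	186658
copy number gain	169876
copy number variation	169191
Others	17810
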