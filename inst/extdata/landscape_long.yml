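patch_length: 16.0
patch_width: 10.0
corridor_length: 20.0
corridor_width: 2.5
fragmentation: Long
has_corridor: yes
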