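hope
anxiety
resignation
acceptance
wonder
avoidance
sharing
scepticism
relief
fear of movement
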