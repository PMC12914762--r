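((((((A:0.006,B:0.009):0.004,C:0.012):0.003,(D:0.007,E:0.011):0.005):0.004,F:0.016):0.003,(G:0.010,(H:0.006,I:0.013):0.005):0.004):0.008,J:0.035);
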