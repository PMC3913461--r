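{"time_ms":0,"kind":"power on","timestamp":"2012-03-01 14:30:00"}
{"time_ms":903300,"kind":"shock delivered","energy_j":150,"impedance_ohm":85}
{"time_ms":1062000,"kind":"recording end"}
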