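qualification	years
College or University degree	20
NVQ or HND or HNC or equivalent	19
Other professional qualifications	15
A levels/AS levels or equivalent	13
O levels/GCSEs or equivalent	10
CSEs or equivalent	10
None of the above	7
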