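{"name":"generic-3.0-18","rings":10,"crowns_per_ring":8,"links_per_ring_pair":3,"link_phase":[1,3,6],"strut_profile":{"shape":"rectangular","width":0.09,"thickness":0.074},"nominal_diameter_mm":3,"nominal_length_mm":18,"crown_fraction":0.8}
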