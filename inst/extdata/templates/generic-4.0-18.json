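{"name":"generic-4.0-18","rings":10,"crowns_per_ring":10,"links_per_ring_pair":3,"link_phase":[1,4,7],"strut_profile":{"shape":"circular","diameter":0.091},"nominal_diameter_mm":4,"nominal_length_mm":18,"crown_fraction":0.8}
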