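{"name":"generic-2.5-16","rings":9,"crowns_per_ring":8,"links_per_ring_pair":3,"link_phase":[1,3,6],"strut_profile":{"shape":"circular","diameter":0.081},"nominal_diameter_mm":2.5,"nominal_length_mm":16,"crown_fraction":0.8}
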