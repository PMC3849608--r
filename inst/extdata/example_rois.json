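[{"roi_id":"tumour_1","core_id":"core_A","polygon":[[20,20],[20,236],[236,236],[236,20]]},{"roi_id":"tumour_2","core_id":"core_A","polygon":[[300,40],[300,200],[480,200],[480,40],[390,20]]}]
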