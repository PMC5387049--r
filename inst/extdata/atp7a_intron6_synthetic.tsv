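gene	intron_ordinal	donor_region	acceptor_region
ATP7A	6	guaaguaagaccuuacuacuuaccuacuuccauaccuuacuaccuuacuguaagaccuac	uuuuccuuag
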