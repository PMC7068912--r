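accession	organism	length_nt
AM777385	Lolium perenne	135282
AP005672	Physcomitrella patens	122890
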