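type,hydrophilic,acceptor,donor,hydrophobic,aromatic,neutral,neutral_donor,neutral_acceptor
hydrophilic,F,F,F,U,U,F,F,F
acceptor,F,U,F,U,U,F,F,U
donor,F,F,U,U,F,F,U,F
hydrophobic,U,U,U,F,F,F,U,U
aromatic,U,U,F,F,F,F,F,U
neutral,F,F,F,F,F,F,F,F
neutral_donor,F,F,U,U,F,F,U,F
neutral_acceptor,F,U,F,U,U,F,F,U
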