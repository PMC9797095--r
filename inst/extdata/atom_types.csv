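base,name,type
*,P,neutral
*,OP1,acceptor
*,OP2,acceptor
*,OP3,acceptor
*,O5',acceptor
*,O3',acceptor
*,O4',acceptor
*,O2',hydrophilic
*,C1',hydrophobic
*,C2',hydrophobic
*,C3',hydrophobic
*,C4',hydrophobic
*,C5',hydrophobic
A,N9,neutral
A,C8,aromatic
A,N7,acceptor
A,C5,aromatic
A,C6,aromatic
A,N6,donor
A,N1,acceptor
A,C2,aromatic
A,N3,acceptor
A,C4,aromatic
G,N9,neutral
G,C8,aromatic
G,N7,acceptor
G,C5,aromatic
G,C6,aromatic
G,O6,acceptor
G,N1,donor
G,C2,aromatic
G,N2,donor
G,N3,acceptor
G,C4,aromatic
C,N1,neutral
C,C2,aromatic
C,O2,acceptor
C,N3,acceptor
C,C4,aromatic
C,N4,donor
C,C5,aromatic
C,C6,aromatic
U,N1,neutral
U,C2,aromatic
U,O2,acceptor
U,N3,donor
U,C4,aromatic
U,O4,acceptor
U,C5,aromatic
U,C6,aromatic
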