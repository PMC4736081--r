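# 2-D multiplexing demonstration workflow on fixtures: two polycistronic
# tRNA-gRNA level 1 structures (2 + 3 guides), their binary combination into
# a level 2 construct, and the addition of a Cas9 TU (hosted in omega via
# its own binary step with a marker TU).
seed: 1
constructs:
  - id: polyXT
    op: polycistron
    targets: [GCATGCCGTAAACGACTAGT, GATTACGTAATACAAAGCTT]
    destination: alpha1
  - id: polyFucT
    op: polycistron
    targets: [GTCGTCCTATTCATCAGAAA, GTATTAGGCAACCTCAATCA, GCCACTCGTAGCTTGATAAC]
    destination: alpha2
  - id: level2
    op: binary
    a: polyXT
    b: polyFucT
    destination: omega1
  - id: cas9
    op: cas9_tu
    destination: alpha1
  - id: marker
    op: marker_tu
    destination: alpha2
  - id: cas9omega
    op: binary
    a: cas9
    b: marker
    destination: omega2
  - id: final
    op: binary
    a: level2
    b: cas9omega
    destination: alpha1
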