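nodes:
- name: all
  parent: .na.character
  gates: []
- name: viable
  parent: all
  gates:
  - channel: viability
    sign: '-'
    threshold: 0.0
- name: Lin-
  parent: viable
  gates:
  - channel: CD45
    sign: '-'
    threshold: 0.0
  - channel: Tie2
    sign: '-'
    threshold: 0.0
  - channel: Ter119
    sign: '-'
    threshold: 0.0
- name: mCherry+
  parent: Lin-
  gates:
  - channel: mCherry
    sign: +
    threshold: 0.0
- name: BCSP
  parent: mCherry+
  gates:
  - channel: CD51
    sign: +
    threshold: 0.0
  - channel: Thy
    sign: '-'
    threshold: 0.0
  - channel: 6C3
    sign: '-'
    threshold: 0.0
  - channel: CD105
    sign: +
    threshold: 0.0
- name: SSC
  parent: mCherry+
  gates:
  - channel: CD51
    sign: +
    threshold: 0.0
  - channel: Thy
    sign: '-'
    threshold: 0.0
  - channel: 6C3
    sign: '-'
    threshold: 0.0
  - channel: CD105
    sign: '-'
    threshold: 0.0
  - channel: CD200
    sign: +
    threshold: 0.0
- name: preBCSP
  parent: mCherry+
  gates:
  - channel: CD51
    sign: +
    threshold: 0.0
  - channel: Thy
    sign: '-'
    threshold: 0.0
  - channel: 6C3
    sign: '-'
    threshold: 0.0
  - channel: CD105
    sign: '-'
    threshold: 0.0
  - channel: CD200
    sign: '-'
    threshold: 0.0
populations:
- BCSP
- SSC
- preBCSP
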