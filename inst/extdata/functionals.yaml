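# Catalog of the 11 density functionals in the benchmark grid.
# hf_sr / hf_mr / hf_lr: percent exact Hartree-Fock exchange at short,
# middle and long interelectronic range. Global hybrids (and the pure GGA)
# carry one constant fraction across all three ranges; range-separated
# hybrids vary it. HISSbPBE applies exchange only in the middle range.
functionals:
  - name: BLYP
    rung: GGA
    meta: false
    hf_sr: 0
    hf_mr: 0
    hf_lr: 0
  - name: TPSSh
    rung: GH
    meta: true
    hf_sr: 10
    hf_mr: 10
    hf_lr: 10
  - name: B3LYP
    rung: GH
    meta: false
    hf_sr: 20
    hf_mr: 20
    hf_lr: 20
  - name: PW6B95
    rung: GH
    meta: true
    hf_sr: 28
    hf_mr: 28
    hf_lr: 28
  - name: MPWB1K
    rung: GH
    meta: true
    hf_sr: 44
    hf_mr: 44
    hf_lr: 44
  - name: M06-2X
    rung: GH
    meta: true
    hf_sr: 54
    hf_mr: 54
    hf_lr: 54
  - name: WB97
    rung: RSH
    meta: false
    hf_sr: 0
    hf_mr: 0
    hf_lr: 100
  - name: WB97X
    rung: RSH
    meta: false
    hf_sr: 15.77
    hf_mr: 0
    hf_lr: 100
  - name: CAM-B3LYP
    rung: RSH
    meta: false
    hf_sr: 19
    hf_mr: 0
    hf_lr: 65
  - name: M11
    rung: RSH
    meta: true
    hf_sr: 42.8
    hf_mr: 0
    hf_lr: 100
  - name: HISSbPBE
    rung: RSH
    meta: false
    hf_sr: 0
    hf_mr: 60
    hf_lr: 0
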