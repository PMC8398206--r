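# Catalog of the 14 basis sets in the benchmark grid.
# nbf: number of basis functions the set assigns to the benchmark molecule
# (caffeic acid). zeta: valence splitting (double or triple). diffuse: TRUE
# if the set carries diffuse functions ("+"/"++"/"aug-"/"D" variants); no
# distinction is made between single and double diffusion.
basis_sets:
  - name: 6-31G(d,p)
    family: Pople
    nbf: 235
    zeta: double
    diffuse: false
  - name: 6-31+G(d,p)
    family: Pople
    nbf: 287
    zeta: double
    diffuse: true
  - name: 6-31++G(d,p)
    family: Pople
    nbf: 295
    zeta: double
    diffuse: true
  - name: 6-311G(d,p)
    family: Pople
    nbf: 282
    zeta: triple
    diffuse: false
  - name: 6-311+G(d,p)
    family: Pople
    nbf: 334
    zeta: triple
    diffuse: true
  - name: 6-311++G(d,p)
    family: Pople
    nbf: 342
    zeta: triple
    diffuse: true
  - name: cc-pVDZ
    family: Dunning
    nbf: 222
    zeta: double
    diffuse: false
  - name: aug-cc-pVDZ
    family: Dunning
    nbf: 371
    zeta: double
    diffuse: true
  - name: cc-pVTZ
    family: Dunning
    nbf: 502
    zeta: triple
    diffuse: false
  - name: aug-cc-pVTZ
    family: Dunning
    nbf: 782
    zeta: triple
    diffuse: true
  - name: def2-SVP
    family: Ahlrich
    nbf: 222
    zeta: double
    diffuse: false
  - name: def2-SVPD
    family: Ahlrich
    nbf: 336
    zeta: double
    diffuse: true
  - name: def2-TZVP
    family: Ahlrich
    nbf: 451
    zeta: triple
    diffuse: false
  - name: def2-TZVPD
    family: Ahlrich
    nbf: 565
    zeta: triple
    diffuse: true
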