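n_loci: 31
intercepts:
  A: 8.29138
  B: 1.17567
  RGRini: 0.00172
  P3: 2695.739999999999782
  kstone: 0.19725
  Wstone: 3.86701
  SLA: 0.02103
effects:
- parameter: A
  locus: 3
  effect: 2.66318
- parameter: A
  locus: 7
  effect: -4.17002
- parameter: A
  locus: 12
  effect: 2.55744
- parameter: A
  locus: 20
  effect: 2.51455
- parameter: A
  locus: 23
  effect: 3.07437
- parameter: A
  locus: 26
  effect: 3.55207
- parameter: B
  locus: 9
  effect: -0.25238
- parameter: B
  locus: 27
  effect: -0.20475
- parameter: RGRini
  locus: 1
  effect: 0.00059
- parameter: RGRini
  locus: 14
  effect: 0.00038
- parameter: RGRini
  locus: 17
  effect: 0.00066
- parameter: RGRini
  locus: 22
  effect: 0.00119
- parameter: RGRini
  locus: 25
  effect: -0.00041
- parameter: RGRini
  locus: 31
  effect: 0.00079
- parameter: P3
  locus: 14
  effect: -227.639999999999986
- parameter: P3
  locus: 18
  effect: -168.949999999999989
- parameter: P3
  locus: 22
  effect: -260.25
- parameter: P3
  locus: 25
  effect: 129.0
- parameter: P3
  locus: 30
  effect: -278.730000000000018
- parameter: kstone
  locus: 4
  effect: -0.03115
- parameter: kstone
  locus: 8
  effect: -0.02533
- parameter: kstone
  locus: 11
  effect: -0.0174
- parameter: kstone
  locus: 13
  effect: -0.02218
- parameter: kstone
  locus: 16
  effect: -0.02466
- parameter: kstone
  locus: 28
  effect: -0.00724
- parameter: kstone
  locus: 31
  effect: -0.01467
- parameter: Wstone
  locus: 2
  effect: 1.33592
- parameter: Wstone
  locus: 6
  effect: 0.92848
- parameter: Wstone
  locus: 14
  effect: 1.83601
- parameter: Wstone
  locus: 19
  effect: -0.22232
- parameter: Wstone
  locus: 24
  effect: -2.02367
- parameter: Wstone
  locus: 29
  effect: 1.33883
- parameter: SLA
  locus: 5
  effect: -0.00077
- parameter: SLA
  locus: 10
  effect: -0.00158
- parameter: SLA
  locus: 15
  effect: -0.00133
- parameter: SLA
  locus: 21
  effect: -0.00061
- parameter: SLA
  locus: 26
  effect: -0.00081
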