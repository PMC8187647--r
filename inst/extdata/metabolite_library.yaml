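reference:
  name: TSP
  concentration_mM: 0.2915
  protons: 9
  t1: 3.0
  shift: 0.0
  search_window:
  - -0.05
  - 0.05
  quant_region:
  - -0.03
  - 0.03
metabolites:
- name: Leucine
  center: 0.92
  pattern: doublet
  j: 6.6
  protons: 6
  t1: 1.3
  quant_region:
  - 0.884501191409
  - 0.955498808591
- name: Valine
  center: 1.02
  pattern: doublet
  j: 7.0
  protons: 6
  t1: 1.2
  quant_region:
  - 0.984167930282
  - 1.055832069718
- name: Isoleucine
  center: 1.12
  pattern: doublet
  j: 6.9
  protons: 3
  t1: 1.3
  quant_region:
  - 1.084251245563
  - 1.155748754437
- name: Lactate
  center: 1.33
  pattern: doublet
  j: 6.9
  protons: 3
  t1: 1.8
  quant_region:
  - 1.294251245563
  - 1.365748754437
- name: Alanine
  center: 1.48
  pattern: doublet
  j: 7.2
  protons: 3
  t1: 1.5
  quant_region:
  - 1.444001299718
  - 1.515998700282
- name: Acetate
  center: 1.92
  pattern: singlet
  j: 0.0
  protons: 3
  t1: 2.5
  quant_region:
  - 1.89
  - 1.95
- name: Glutamate
  center: 2.05
  pattern: triplet
  j: 7.5
  protons: 2
  t1: 1.2
  quant_region:
  - 2.007502707747
  - 2.092497292253
- name: Glutamine
  center: 2.17
  pattern: triplet
  j: 7.6
  protons: 2
  t1: 1.2
  quant_region:
  - 2.127336077183
  - 2.212663922817
- name: Pyruvate
  center: 2.28
  pattern: singlet
  j: 0.0
  protons: 3
  t1: 1.6
  quant_region:
  - 2.25
  - 2.31
- name: Succinate
  center: 2.41
  pattern: singlet
  j: 0.0
  protons: 4
  t1: 1.8
  quant_region:
  - 2.38
  - 2.44
- name: Citrate
  center: 2.66
  pattern: doublet
  j: 15.5
  protons: 2
  t1: 1.2
  quant_region:
  - 2.617086131338
  - 2.702913868662
- name: Aspartate
  center: 2.81
  pattern: doublet
  j: 17.4
  protons: 1
  t1: 1.0
  quant_region:
  - 2.765503140986
  - 2.854496859014
- name: Creatine
  center: 3.04
  pattern: singlet
  j: 0.0
  protons: 3
  t1: 1.4
  quant_region:
  - 3.01
  - 3.07
- name: Taurine
  center: 3.26
  pattern: triplet
  j: 6.6
  protons: 2
  t1: 1.8
  quant_region:
  - 3.219002382817
  - 3.300997617183
- name: Glycine
  center: 3.56
  pattern: singlet
  j: 0.0
  protons: 2
  t1: 1.4
  quant_region:
  - 3.53
  - 3.59
- name: 3-hydroxybutytrate
  center: 4.13
  pattern: quartet
  j: 6.3
  protons: 1
  t1: 1.6
  quant_region:
  - 4.084253411761
  - 4.175746588239
- name: Glucose
  center: 5.23
  pattern: doublet
  j: 3.8
  protons: 1
  t1: 1.6
  quant_region:
  - 5.196834019296
  - 5.263165980704
- name: Uracil
  center: 5.8
  pattern: doublet
  j: 7.7
  protons: 1
  t1: 2.6
  quant_region:
  - 5.76358472331
  - 5.83641527669
- name: Uridine
  center: 5.92
  pattern: doublet
  j: 8.1
  protons: 1
  t1: 2.4
  quant_region:
  - 5.883251462183
  - 5.956748537817
- name: Fumarate
  center: 6.52
  pattern: singlet
  j: 0.0
  protons: 2
  t1: 3.0
  quant_region:
  - 6.49
  - 6.55
- name: Tyrosine
  center: 6.9
  pattern: doublet
  j: 8.5
  protons: 2
  t1: 2.0
  quant_region:
  - 6.862918201056
  - 6.937081798944
- name: Histidine
  center: 7.09
  pattern: singlet
  j: 0.0
  protons: 1
  t1: 1.9
  quant_region:
  - 7.06
  - 7.12
- name: Phenylalanine
  center: 7.42
  pattern: triplet
  j: 7.4
  protons: 1
  t1: 2.2
  quant_region:
  - 7.37766933831
  - 7.46233066169
- name: Carnosine
  center: 8.07
  pattern: singlet
  j: 0.0
  protons: 1
  t1: 2.0
  quant_region:
  - 8.04
  - 8.1
- name: Hypoxanthine
  center: 8.19
  pattern: singlet
  j: 0.0
  protons: 1
  t1: 2.8
  quant_region:
  - 8.16
  - 8.22
- name: Inosine
  center: 8.34
  pattern: singlet
  j: 0.0
  protons: 1
  t1: 2.6
  quant_region:
  - 8.31
  - 8.37
- name: Formate
  center: 8.46
  pattern: singlet
  j: 0.0
  protons: 1
  t1: 4.0
  quant_region:
  - 8.43
  - 8.49
- name: ADP
  center: 8.58
  pattern: singlet
  j: 0.0
  protons: 1
  t1: 2.8
  quant_region:
  - 8.55
  - 8.61
- name: AMP
  center: 8.7
  pattern: singlet
  j: 0.0
  protons: 1
  t1: 2.8
  quant_region:
  - 8.67
  - 8.73
- name: Nicotinamide
  center: 8.94
  pattern: singlet
  j: 0.0
  protons: 1
  t1: 2.6
  quant_region:
  - 8.91
  - 8.97
- name: NAD
  center: 9.33
  pattern: singlet
  j: 0.0
  protons: 1
  t1: 2.2
  quant_region:
  - 9.3
  - 9.36
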