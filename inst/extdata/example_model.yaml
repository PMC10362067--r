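contig: igh_sim
locus_length: 1200000
genes:
- name: IGHJ4
  segment: J
  position: 2000
  functional: yes
- name: IGHJ6
  segment: J
  position: 3000
  functional: yes
- name: IGHD3-3
  segment: D
  position: 20000
  functional: yes
- name: IGHD4-4
  segment: D
  position: 24000
  functional: yes
- name: IGHD3-9
  segment: D
  position: 28000
  functional: yes
- name: IGHV1-2
  segment: V
  position: 100000
  functional: yes
- name: IGHV3-23
  segment: V
  position: 140000
  functional: yes
- name: IGHV3-23D
  segment: V
  position: 144000
  functional: yes
- name: IGHV3-66
  segment: V
  position: 180000
  functional: yes
blocks:
- block: 1
  hap_freq: 0.5
- block: 2
  hap_freq: 0.3
- block: 3
  hap_freq: 0.6
- block: 4
  hap_freq: 0.45
snvs:
- id: s01
  position: 19200
  block: 1
  on_hapA: yes
  containing_sv: DEL1
- id: s02
  position: 19400
  block: 1
  on_hapA: yes
  containing_sv: DEL1
- id: s03
  position: 19600
  block: 1
  on_hapA: yes
  containing_sv: DEL1
- id: s04
  position: 50000
  block: 2
  on_hapA: yes
  containing_sv: .na.character
- id: s05
  position: 50200
  block: 2
  on_hapA: yes
  containing_sv: .na.character
- id: s06
  position: 50400
  block: 2
  on_hapA: yes
  containing_sv: .na.character
- id: s07
  position: 90000
  block: 3
  on_hapA: yes
  containing_sv: .na.character
- id: s08
  position: 90200
  block: 3
  on_hapA: yes
  containing_sv: .na.character
- id: s09
  position: 90400
  block: 3
  on_hapA: yes
  containing_sv: .na.character
- id: s10
  position: 181000
  block: 4
  on_hapA: yes
  containing_sv: .na.character
- id: s11
  position: 181200
  block: 4
  on_hapA: yes
  containing_sv: .na.character
- id: s12
  position: 181400
  block: 4
  on_hapA: yes
  containing_sv: .na.character
effects:
- variant: s10
  gene: IGHV3-66
  multiplier: 1.8
coding_alleles:
- gene: IGHV3-66
  tag_snv: s10
  ref_label: '*03'
  alt_label: '*01'
baseline_weights:
  IGHJ4: 1.0
  IGHJ6: 1.5
  IGHD3-3: 0.8
  IGHD4-4: 1.2
  IGHD3-9: 1.0
  IGHV1-2: 2.0
  IGHV3-23: 1.4
  IGHV3-23D: 1.4
  IGHV3-66: 0.9
svs:
  DEL1:
    id: DEL1
    span:
    - 19000
    - 25000
    alleles:
    - name: REF
      freq: 0.7
    - name: DEL
      freq: 0.3
    copy_map:
      REF:
        IGHD3-3: 1.0
        IGHD4-4: 1.0
      DEL:
        IGHD3-3: 0.0
        IGHD4-4: 0.0
    deleted_ranges:
      DEL:
      - - 19000
        - 25000
covariate_model:
  age_range:
  - 18.0
  - 75.0
  age_slope:
    IGHJ4: 0.0
    IGHJ6: 0.0
    IGHD3-3: 0.0
    IGHD4-4: 0.0
    IGHD3-9: 0.0
    IGHV1-2: 0.0
    IGHV3-23: 0.0
    IGHV3-23D: 0.0
    IGHV3-66: 0.0
  platforms:
  - P1
  - P2
  - P3
  platform_probs:
  - 0.5
  - 0.3
  - 0.2
  platform_effects:
    IGHJ4:
      P1: 1.0
      P2: 1.0
      P3: 1.0
    IGHJ6:
      P1: 1.0
      P2: 1.0
      P3: 1.0
    IGHD3-3:
      P1: 1.0
      P2: 1.0
      P3: 1.0
    IGHD4-4:
      P1: 1.0
      P2: 1.0
      P3: 1.0
    IGHD3-9:
      P1: 1.0
      P2: 1.0
      P3: 1.0
    IGHV1-2:
      P1: 1.0
      P2: 1.0
      P3: 1.0
    IGHV3-23:
      P1: 1.0
      P2: 1.0
      P3: 1.0
    IGHV3-23D:
      P1: 1.0
      P2: 1.0
      P3: 1.0
    IGHV3-66:
      P1: 1.0
      P2: 1.0
      P3: 1.0
noise_sd: 0.2
clone_model:
  mean_clones: 9038.0
  dispersion: 8.0
  min_clones: 500.0
  dup_geom_prob: 0.35
  junction_range:
  - 30
  - 70
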