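{
 "comment": "exosome core subunit mutant; ITS-dominated antisense mass",
 "n_reads": 100000,
 "seed": 1,
 "fractions": {
  "risiRNA": 0.25,
  "sense_rRNA": 0.45,
  "sense_mRNA": 0.15,
  "antisense_mRNA": 0.05,
  "unmapped": 0.1
 },
 "region_weights": {
  "5ETS": 0.05,
  "18S": 0.1,
  "ITS1": 0.3,
  "5.8S": 0.04,
  "ITS2": 0.3,
  "26S": 0.18,
  "3ETS": 0.03
 },
 "length_dist": {
  "18": 0.01,
  "19": 0.02,
  "20": 0.05,
  "21": 0.12,
  "22": 0.55,
  "23": 0.12,
  "24": 0.06,
  "25": 0.03,
  "26": 0.02,
  "27": 0.01,
  "28": 0.005,
  "29": 0.003,
  "30": 0.002
 },
 "p_first_G": 0.75,
 "frac_rRNA_5S": 0.1
}
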