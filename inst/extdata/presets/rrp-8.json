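{
 "comment": "26S rRNA m1A methyltransferase mutant; 26S-dominated",
 "n_reads": 100000,
 "seed": 1,
 "fractions": {
  "risiRNA": 0.2,
  "sense_rRNA": 0.5,
  "sense_mRNA": 0.15,
  "antisense_mRNA": 0.05,
  "unmapped": 0.1
 },
 "region_weights": {
  "5ETS": 0.04,
  "18S": 0.1,
  "ITS1": 0.05,
  "5.8S": 0.02,
  "ITS2": 0.06,
  "26S": 0.7,
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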