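{
 "comment": "baseline total small-RNA library; scarce risiRNAs, antisense mass proportional to region length",
 "n_reads": 100000,
 "seed": 1,
 "fractions": {
  "risiRNA": 0.02,
  "sense_rRNA": 0.55,
  "sense_mRNA": 0.28,
  "antisense_mRNA": 0.05,
  "unmapped": 0.1
 },
 "region_weights": {
  "5ETS": 700,
  "18S": 1750,
  "ITS1": 500,
  "5.8S": 160,
  "ITS2": 350,
  "26S": 3500,
  "3ETS": 150
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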