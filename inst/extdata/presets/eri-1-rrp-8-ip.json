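{
 "comment": "NRDE-3 immunoprecipitation library, eri-1;rrp-8 background; 90% of antisense mass in 26S",
 "n_reads": 100000,
 "seed": 1,
 "fractions": {
  "risiRNA": 0.6,
  "sense_rRNA": 0.1,
  "sense_mRNA": 0.05,
  "antisense_mRNA": 0.2,
  "unmapped": 0.05
 },
 "region_weights": {
  "5ETS": 0.01,
  "18S": 0.03,
  "ITS1": 0.02,
  "5.8S": 0.01,
  "ITS2": 0.02,
  "26S": 0.9,
  "3ETS": 0.01
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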