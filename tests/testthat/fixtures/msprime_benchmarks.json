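{
 "constant": {
  "config": {
   "n": 10,
   "Ne": 1000,
   "mu": 1e-06,
   "L": 1000
  },
  "mean_S": 11.3357,
  "mean_pi": 4.0102199999999995,
  "mean_tmrca": 3609.298435944885
 },
 "split": {
  "config": {
   "n": [
    5,
    5
   ],
   "Ne": 500,
   "T": 2000,
   "mu": 1e-06,
   "L": 1000
  },
  "mean_S": 11.0938,
  "mean_pi": 4.214455555555555,
  "mean_tmrca": 3160.348935440883
 },
 "expansion": {
  "config": {
   "n": 20,
   "Ne1": 10000,
   "Ne0": 100,
   "T": 1000,
   "mu": 1e-06,
   "L": 1000
  },
  "mean_S": 17.67055,
  "mean_pi": 2.34082052631579,
  "mean_tmrca": 1367.8368645197575
 }
}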