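U50 | C3m   Decennial COL from age 50 to 70                               Short-term delay (3 months)
U50 | C9m   Decennial COL from age 50 to 70                               Short-term delay (9 months)
U50 | C18m  Decennial COL from age 50 to 70                               Short-term delay (18 months)
U50 | C@65  Decennial COL from age 50 to 70                               Long-term delay (COL at age 65 and 75)
U50 | F3m   Annual FIT from age 50 to 75                                  Short-term delay (3 months)
U50 | F9m   Annual FIT from age 50 to 75                                  Short-term delay (9 months)
U50 | F18m  Annual FIT from age 50 to 75                                  Short-term delay (18 months)
U60 | C3m   Decennial COL from age 60 to 70                               Short-term delay (3 months)
U60 | C9m   Decennial COL from age 60 to 70                               Short-term delay (9 months)
U60 | C18m  Decennial COL from age 60 to 70                               Short-term delay (18 months)
U60 | C@65  Decennial COL from age 60 to 70                               Long-term delay (COL at age 65 and 75)
U60 | F3m   Annual FIT from age 60 to 75                                  Short-term delay (3 months)
U60 | F9m   Annual FIT from age 60 to 75                                  Short-term delay (9 months)
U60 | F18m  Annual FIT from age 60 to 75                                  Short-term delay (18 months)
C60 | C3m   Decennial COL from age 50 to 70                               Short-term delay (3 months)
C60 | C9m   Decennial COL from age 50 to 70                               Short-term delay (9 months)
C60 | C18m  Decennial COL from age 50 to 70                               Short-term delay (18 months)
C60 | F3m   Decennial COL from age 50 to 70                               Switch to annual FIT, delayed 3 months
C60 | F9m   Decennial COL from age 50 to 70                               Switch to annual FIT, delayed 9 months
C60 | F18m  Decennial COL from age 50 to 70                               Switch to annual FIT, delayed 18 months
C60 | C@65  Decennial COL from age 50 to 70                               Long-term delay (COL at age 65 and 75)
C60 | U     Decennial COL from age 50 to 70                               Discontinue screening
F60 | F3m   Annual FIT from age 50 to 75                                  Short-term delay (3 months)
F60 | F9m   Annual FIT from age 50 to 75                                  Short-term delay (9 months)
F60 | F18m  Annual FIT from age 50 to 75                                  Short-term delay (18 months)
F60 | U     Annual FIT from age 50 to 75                                  Discontinue screening
f60 | F3m   Biannual FIT from age 50 to 56, annual FIT from age 60 to 75  Short-term delay (3 months)
f60 | F9m   Biannual FIT from age 50 to 56, annual FIT from age 60 to 75  Short-term delay (9 months)
f60 | F18m  Biannual FIT from age 50 to 56, annual FIT from age 60 to 75  Short-term delay (18 months)
f60 | U     Biannual FIT from age 50 to 56, annual FIT from age 60 to 75  Discontinue screening
U70 | C3m   COL at age 70                                                 Short-term delay (3 months)
U70 | C9m   COL at age 70                                                 Short-term delay (9 months)
U70 | C18m  COL at age 70                                                 Short-term delay (18 months)
U70 | C@75  COL at age 70                                                 Long-term delay (COL at age 75)
U70 | F3m   Annual FIT from age 70 to 75                                  Short-term delay (3 months)
U70 | F9m   Annual FIT from age 70 to 75                                  Short-term delay (9 months)
U70 | F18m  Annual FIT from age 70 to 75                                  Short-term delay (18 months)
C70 | C3m   Decennial COL from age 50 to 70                               Short-term delay (3 months)
C70 | C9m   Decennial COL from age 50 to 70                               Short-term delay (9 months)
C70 | C18m  Decennial COL from age 50 to 70                               Short-term delay (18 months)
C70 | F3m   Decennial COL from age 50 to 70                               Switch to annual FIT, delayed 3 months
C70 | F9m   Decennial COL from age 50 to 70                               Switch to annual FIT, delayed 9 months
C70 | F18m  Decennial COL from age 50 to 70                               Switch to annual FIT, delayed 18 months
C70 | C@75  Decennial COL from age 50 to 70                               Long-term delay (COL at age 75)
C70 | U     Decennial COL from age 50 to 70                               Discontinue screening
F70 | F3m   Annual FIT from age 50 to 75                                  Short-term delay (3 months)
F70 | F9m   Annual FIT from age 50 to 75                                  Short-term delay (9 months)
F70 | F18m  Annual FIT from age 50 to 75                                  Short-term delay (18 months)
F70 | U     Annual FIT from age 50 to 75                                  Discontinue screening
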