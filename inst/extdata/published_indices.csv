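Name,Index,Published,Status,Corrected,Note
Thalidomide,ABC_R,5.9115,verbatim,,
Thalidomide,GA,2.3429,erratum,20.3429,six-step worked example computes 20.3429; table drops the leading digit
Thalidomide,EPi1,1467,erratum,1.46766e45,worked example renders 1.46766e45; table keeps four mantissa digits only
Thalidomide,EPi2,1430,erratum,1.43020e55,worked example renders 1.43020e55; table keeps four mantissa digits only
Thalidomide,GAPi,570.213,verbatim,,
Thalidomide,SDD,48.3333,verbatim,,
Aspirin,ABC_R,3.44,verbatim,,
Aspirin,GA,12.3833,verbatim,,
Aspirin,EPi1,1420,erratum,1.1420e26,computed mantissa 1.1420 matches the printed digits; power of ten omitted
Aspirin,EPi2,4.607,erratum,4.6071e28,computed mantissa 4.607 matches the printed value; power of ten omitted
Aspirin,GAPi,81.4590,verbatim,,
Aspirin,SDD,32,verbatim,,
Valproic Acid,ABC_R,1.8235,verbatim,,
Valproic Acid,GA,5.2314,erratum,,structure-derived value is 8.5773; kept verbatim (study regressions used the printed value)
Valproic Acid,EPi1,3.1856,erratum,3.1856e16,computed mantissa 3.1856 matches the printed value; power of ten omitted
Valproic Acid,EPi2,8.659e16,verbatim,,
Valproic Acid,GAPi,0.8000,erratum,,structure-derived value is 12.8006
Valproic Acid,SDD,22,verbatim,,
Celecoxib,ABC_R,9.2836,erratum,,inconsistent with the edge partition confirmed by the other five columns (recomputed 8.5637)
Celecoxib,GA,26.4031,verbatim,,
Celecoxib,EPi1,4.6754e64,erratum,4.6754e61,printed mantissa matches exp(142) exactly; printed power of ten is off by three
Celecoxib,EPi2,1.2384e72,verbatim,,
Celecoxib,GAPi,1160.9528,verbatim,,
Celecoxib,SDD,73,verbatim,,
Leflunomide,ABC_R,5.8192,verbatim,,
Leflunomide,GA,18.9602,verbatim,,
Leflunomide,EPi1,2.2353e37,erratum,,implies sum of squared degrees 86; the partition confirmed by ABC-R/SDD/EPi2 gives 98
Leflunomide,EPi2,4.3750e48,verbatim,,
Leflunomide,GAPi,257.9914,verbatim,,
Leflunomide,SDD,50.8333,verbatim,,
Wortmannin,ABC_R,10.3553,verbatim,,
Wortmannin,GA,33.5562,verbatim,,
Wortmannin,EPi1,8.1318e79,verbatim,,
Wortmannin,EPi2,8.4682e102,verbatim,,
Wortmannin,GAPi,6449.763,verbatim,,
Wortmannin,SDD,84.3333,verbatim,,
Zoledronic Acid,ABC_R,5.1584,verbatim,,
Zoledronic Acid,GA,13.4822,erratum,,structure-derived value is 14.4822 (printed value one unit lower); kept verbatim
Zoledronic Acid,EPi1,3.0251e36,verbatim,,
Zoledronic Acid,EPi2,3.6379e42,verbatim,,
Zoledronic Acid,GAPi,77.5959,erratum,,structure-derived value is 93.1151
Zoledronic Acid,SDD,48.75,verbatim,,
Minocycline,ABC_R,11.6827,verbatim,,
Minocycline,GA,35.653,verbatim,,
Minocycline,EPi1,3.9452e88,verbatim,,
Minocycline,EPi2,1.6575e114,verbatim,,
Minocycline,GAPi,8774.3495,erratum,,structure-derived value is 9030.26
Minocycline,SDD,99.75,verbatim,,
Metformin,ABC_R,2.1268,verbatim,,
Metformin,GA,7.2897,verbatim,,
Metformin,EPi1,4.3112e15,verbatim,,
Metformin,EPi2,4.3112e15,verbatim,,
Metformin,GAPi,8.4853,verbatim,,
Metformin,SDD,23,verbatim,,
Thiocolchicoside,ABC_R,11.2285,verbatim,,
Thiocolchicoside,GA,40.6037,verbatim,,
Thiocolchicoside,EPi1,2.9152e89,verbatim,,
Thiocolchicoside,EPi2,3.7465e108,verbatim,,
Thiocolchicoside,GAPi,8294.384,verbatim,,
Thiocolchicoside,SDD,97,verbatim,,
Noscapine,ABC_R,9.2942,erratum,,"printed row is internally inconsistent; no graph reproduces ABC-R, SDD and GA together"
Noscapine,GA,33.1743,erratum,,canonical structure gives 33.2978
Noscapine,EPi1,2.7279e76,erratum,,canonical structure gives exp(170)
Noscapine,EPi2,4.7445e94,erratum,,canonical structure gives exp(214)
Noscapine,GAPi,1934.7865,erratum,,canonical structure gives 2995.2
Noscapine,SDD,70.75,erratum,,printed row is internally inconsistent; canonical structure gives 74.3333
Nitroxoline,ABC_R,4.0746,verbatim,,
Nitroxoline,GA,14.5173,verbatim,,
Nitroxoline,EPi1,1.8587e31,verbatim,,
Nitroxoline,EPi2,8.2230e36,verbatim,,
Nitroxoline,GAPi,162.9196,verbatim,,
Nitroxoline,SDD,34.6667,verbatim,,
Methotrexate,ABC_R,9.7877,verbatim,,
Methotrexate,GA,33.5645,verbatim,,
Methotrexate,EPi1,9.1511e72,verbatim,,
Methotrexate,EPi2,6.5892e83,verbatim,,
Methotrexate,GAPi,2443.7562,verbatim,,
Methotrexate,SDD,83.6667,verbatim,,
Vesnarinone,ABC_R,8.5599,verbatim,,
Vesnarinone,GA,31.254,verbatim,,
Vesnarinone,EPi1,7.6094e66,verbatim,,
Vesnarinone,EPi2,2.9915e79,verbatim,,
Vesnarinone,GAPi,1440.049,verbatim,,
Vesnarinone,SDD,70.6667,verbatim,,
Simvastatin,ABC_R,9.6039,verbatim,,
Simvastatin,GA,31.2514,verbatim,,
Simvastatin,EPi1,1.2385e72,verbatim,,
Simvastatin,EPi2,9.7793e85,verbatim,,
Simvastatin,GAPi,1146.6172,verbatim,,
Simvastatin,SDD,83.4167,verbatim,,
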