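product_id,protein_g,vitamin_a_ug,vitamin_e_mg,thiamin_mg,riboflavin_mg,niacin_mg,pantothenic_acid_mg,folate_ug,vitamin_b12_ug,vitamin_c_mg,calcium_mg,copper_mg,iron_mg,magnesium_mg,potassium_mg,sodium_mg,zinc_mg,vitamin_b6_mg
oat,7.836,2.484,0.5825,0.3532,0.07539,2.384,1.466,68.67,0,2.536,22.55,0.3637,1.83,94.57,378.7,4.57,4.006,0.4267
barley,16.72,1.655,0.331,0.4479,0.08923,5.851,0.5653,43.38,0,1.897,55.46,0.2271,3.766,132.4,172.9,5.139,1.207,0.3852
wheat,10.48,2.8,0.798,0.3163,0.08203,4.093,0.7908,49.09,0,2.965,41.01,0.4955,2.546,80.18,406.3,4.116,3.784,0.4743
potato,5.637,1.419,0.746,0.3274,0.106,5.586,0.6488,26.84,0,4.359,51.73,0.4277,2.662,135.4,242.3,4.254,1.794,0.2275
bean,38.11,3.569,0.7856,0.3048,0.2737,1.895,0.8025,310.1,0,4.171,87.81,1.072,5.82,117.5,1054,8.447,3.105,0.3696
almond,31.07,1.342,19.07,0.1612,1.152,3.053,0.4562,67.42,0,0.692,393.1,0.4806,3.839,125.5,887.1,0.6858,2.293,0.1312
milk,2.78,28.69,0.09662,0.02871,0.2598,0.089,0.8082,4.919,0.6897,1.073,169.3,0.02639,0.07475,11.33,345.9,35.81,0.4557,0.05178
beef_meat,13.16,6.128,0.1988,0.1042,0.3863,3.925,1.144,7.195,2.499,0,11.4,0.05809,1.349,25.05,443.9,70.54,4.46,0.4407
camel_meat,12.44,6.837,0.3283,0.1737,0.246,12.35,1.651,9.487,2.823,0,10.38,0.07764,1.876,27.3,342.7,52.11,6.011,0.3369
goat_meat,31.31,7.226,0.4092,0.05036,0.2373,8.501,1.114,9.887,1.867,0,10.43,0.07615,1.955,21.38,498.7,82.52,5.107,0.464
sheep_meat,14.13,5.26,0.3899,0.1051,0.2723,5.366,1.042,8.744,3.083,0,13.88,0.124,2.055,18.71,466.4,79.39,2.485,0.4443
poultry_meat,26,3.315,0.3377,0.0703,0.1603,7.856,0.9157,8.07,1.034,0,14.46,0.06009,2.659,42.41,373.7,162.8,4.77,0.7429
egg,31.24,273.8,2.15,0.03206,0.4221,0.08121,2.202,54.94,0.7644,0,36.99,0.04808,1.422,21,304.5,136.6,2.146,0.1523
chard,1.137,226.8,1.719,0.03457,0.06446,0.2552,0.1843,225.6,0,16.51,47.69,0.2313,1.98,70.31,454.7,135.2,0.4746,0.08755
carrot,1.719,443.5,0.7493,0.07153,0.06129,0.8834,0.2743,83.36,0,47.18,41.8,0.2001,1.227,21.2,482.2,119.6,0.1925,0.2264
parsley,2.351,645.3,0.8449,0.07718,0.03388,0.7009,0.1425,70.94,0,41.58,35.95,0.07796,0.8896,34.01,480.3,57.6,0.1421,0.124
cucumber,1.767,28.33,0.3389,0.08178,0.0261,0.4672,0.3543,22.3,0,6.253,28.08,0.06508,0.5137,10.32,281.1,4.437,0.2711,0.08226
fennel,1.225,17.62,0.6136,0.06884,0.02657,0.452,0.2691,33.2,0,16.15,43.84,0.05558,0.2549,17.55,87.94,6,0.2335,0.08707
onion,1.787,22.08,0.4086,0.0565,0.03996,0.5195,0.1633,30.04,0,7.983,17.26,0.06833,0.4226,12.48,283.4,5.336,0.3062,0.1081
pea,1.08,27.83,0.4381,0.03692,0.06219,0.7381,0.2418,35.34,0,14.41,35.61,0.09021,0.5397,20.39,230.7,8.354,0.2322,0.06782
squash,2.03,14.85,0.8147,0.04325,0.04721,1.168,0.3203,17.68,0,20.15,10.99,0.04588,0.4403,12.19,229.6,6.302,0.1747,0.09525
tomato,0.8124,20.46,0.3864,0.05698,0.06204,0.3927,0.2268,35.53,0,7.026,18.89,0.07417,0.419,14.74,141.4,5.468,0.3272,0.08221
grape,0.6496,5.594,0.3732,0.03824,0.05563,0.4635,0.1734,4.209,0,49.69,25.62,0.09352,0.6048,10.45,139.2,2.438,0.1291,0.1279
lemon,1.073,2.626,0.2184,0.04045,0.0538,0.3821,0.08827,7.886,0,32.9,11.4,0.1399,0.3492,5.861,112.8,0.8174,0.1201,0.1026
garlic,1.828,7.523,3.491,0.0629,0.0654,0.2536,0.2162,4.689,0,4.099,34.97,0.09786,0.7621,16.26,78.03,281.5,0.4042,0.1815
honey,1.312,6.386,3.892,0.08562,0.04845,0.5088,0.2754,9.068,0,5.599,83.24,0.1188,0.7386,6.933,202.2,432.7,0.7364,0.201
hot_pepper,1.849,2.771,2.077,0.06363,0.03804,0.5347,0.1061,6.894,0,6.166,29.27,0.1286,0.7422,10.99,154,496,0.2668,0.223
olive_oil,1.47,3.111,1.819,0.08579,0.05413,0.4018,0.3205,4.964,0,8.216,30.52,0.08988,1.253,13.79,117.8,225.8,0.1645,0.1406
table_olive,1.678,3.869,2.464,0.1575,0.02477,0.5701,0.4279,4.541,0,3.936,20.57,0.1455,2.12,16.48,176,426.4,0.4872,0.172
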