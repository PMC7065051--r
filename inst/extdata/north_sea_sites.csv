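# Sampling locations, southern North Sea blue-mussel connectivity study.
# Coordinates in decimal degrees WGS1984; dist_shore_km = distance to the
# nearest coastline; is_outgroup marks the two reference populations.
site_id,full_name,structure,n_genotyped,depth_m,lat,lon,dist_shore_km,is_outgroup
BG1x,BG 1,Buoy,44,0,53.8833,3.4983,116,FALSE
BKUM,Borkum Riffgat,Wind farm,25,4,53.69,6.48,14,FALSE
BLYT,Blythe,Pier,48,0,55.1258,-1.4983,0,FALSE
BRES,Breskens,Breakwater,48,0,51.4068,3.5121,0,FALSE
BVW,BV W,Buoy,48,0,52.6007,3.517,74,FALSE
CALA,Calais,Pier,24,0,50.9661,1.8433,0,FALSE
D15A,D15-A,O&G platform,48,7,54.3247,2.9346,181,FALSE
EUR7,EURO 7,Buoy,48,0,51.99,3.5031,32,FALSE
EURW,Euro W,Buoy,48,0,51.9095,2.7232,70,FALSE
F31A,F3-1A,O&G platform,47,5,54.852,4.6949,166,FALSE
FINO,FINO 3,Research platform,28,4,55.195,7.1583,71,FALSE
G14A,G14-A,O&G platform,48,13,54.2241,5.4986,85,FALSE
HARW,Harwich,Pebble beach,42,0,51.9348,1.2813,0,FALSE
HELG,Helgoland,Harbour,48,0,54.176,7.8945,47,FALSE
HORN,Horns Rev,Wind farm,67,0,55.4789,7.811,19,FALSE
K10B,K10-B,O&G platform,48,27,53.3626,3.2539,104,FALSE
K9A,K9-A,O&G platform,48,0,53.5202,3.9925,66,FALSE
L10G,L10-G,O&G platform,48,10,53.4904,4.1952,53,FALSE
L15A,L15-A,O&G platform,48,6,53.3295,4.8302,11,FALSE
LIMF,Limfjorden,Longlines,48,2,56.783,8.911,0,TRUE
LISB,Lisbon,Harbour,37,0,38.7635,-9.0926,0,TRUE
PAAL,Texel,Breakwater,48,0,53.0118,4.7083,0,FALSE
Q13A,Q13-A,O&G platform,48,0,52.1911,4.1361,13,FALSE
SCHV,Scheveningen,Breakwater,48,0,52.0987,4.2582,0,FALSE
SYLT,Sylt,Breakwater,48,0,55.0216,8.4403,0,FALSE
WZA,Wadden Sea A,Intertidal mussel bed,24,0,53.4521,6.3042,0,FALSE
WZB,Wadden Sea B,Subtidal mussel bed,24,2,53.46,6.3583,0,FALSE
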