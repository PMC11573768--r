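# Default identifier sets for bloomloci.
#
# susc_domains / susd_domains are the published PUL-detection domain lists.
# usicg_ids are a SYNTHETIC stand-in panel (the original 11-gene single-copy
# panel is not public): 11 ribosomal/translation COGs expected once per
# genome. carb_related, sulfatase_ids and peptidase_ids are likewise small
# synthetic defaults; real analyses should supply their own curated map.
usicg_ids:
  - COG0048   # ribosomal protein S12
  - COG0049   # ribosomal protein S7
  - COG0052   # ribosomal protein S2
  - COG0080   # ribosomal protein L11
  - COG0081   # ribosomal protein L1
  - COG0087   # ribosomal protein L3
  - COG0088   # ribosomal protein L4
  - COG0090   # ribosomal protein L2
  - COG0091   # ribosomal protein L22
  - COG0092   # ribosomal protein S3
  - COG0093   # ribosomal protein L14
carb_related:
  pfam:
    - PF00128   # alpha-amylase catalytic domain
    - PF00232   # glycoside hydrolase family 1
    - PF00703   # glycoside hydrolase family 2
    - PF00759   # cellulase (GH5)
    - PF01915   # glycoside hydrolase family 3 C-terminal
    - PF02156   # glycoside hydrolase family 26
    - PF02838   # glycoside hydrolase family 20
    - PF13419   # haloacid dehalogenase-like sugar phosphatase
  kegg:
    - K01176    # alpha-amylase
    - K01179    # endoglucanase
    - K01188    # beta-glucosidase
    - K01191    # alpha-mannosidase
    - K05349    # beta-glucosidase (bglX)
  cog:
    - COG0366   # glycosidase
    - COG1472   # beta-glucosidase-related
    - COG2730   # endoglucanase
    - COG3250   # beta-galactosidase/beta-glucuronidase
susc_domains:
  - PF00593    # TonB-dependent receptor
  - PF07715    # TonB-dependent receptor plug domain
  - PF13715    # Carboxy-pepD domain
  - TIGR04056  # SusC/RagA family
susd_domains:
  - PF07980    # SusD family
  - PF12741    # SusD and RagB
  - PF12771    # starch-binding SusD-like
  - PF14322    # starch-binding SusD-like N-terminal
sulfatase_ids:
  - PF00884    # sulfatase domain
peptidase_ids:
  - PF00082    # subtilase peptidase
  - PF01433    # peptidase M1
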