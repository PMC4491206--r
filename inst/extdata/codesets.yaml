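# Default screening code-set registry (ICD-9-CM), version-tagged.
#
# This is a reconstruction assembled from standard ICD-9-CM code families for
# opioid/analgesic poisoning, drug adverse effects in therapeutic use, and
# the serious CNS/respiratory symptoms of opioid toxicity. It is a documented
# default intended for simulation and testing; swap in a study-specific
# registry for real analyses. Patterns are dot-free and match normalized
# codes by prefix unless written with a leading "=" (exact match).
#
# Group semantics per category:
#   A: opioid or unspecified-analgesic codes (always trigger)
#   B: specific non-opioid drug codes (veto the unspecified-medication group)
#   C: unspecified-medication codes (trigger only when no B code is present)
version: "reconstruction-1.0"
categories:
  intentional_overdose:
    # self-inflicted poisoning (E950 family)
    A: ["E9500"]                      # analgesics/antipyretics incl. opioids
    B: ["E9501", "E9502", "E9503",    # barbiturates, sedatives, psychotropics
         "960", "961", "962", "963", "964",
         "9651", "9654", "9655", "9656", "9657", "9658",
         "966", "967", "968", "969", "970", "971", "972", "973",
         "974", "975", "976", "978", "979"]
    C: ["E9504", "E9505"]             # other-specified / unspecified drug
  unintentional_overdose:
    # accidental poisoning (E850/E858) and undetermined intent (E980);
    # opiate poisoning diagnoses 965.0x and unspecified analgesic 965.9
    A: ["9650", "9659",
        "E8500", "E8501", "E8502", "E8509",
        "E9800"]
    B: ["E8503", "E8504", "E8505", "E8506", "E8507", "E8508",
        "E851", "E852", "E853", "E854", "E855", "E856", "E857",
        "E9801", "E9802", "E9803",
        "960", "961", "962", "963", "964",
        "9651", "9654", "9655", "9656", "9657", "9658",
        "966", "967", "968", "969", "970", "971", "972", "973",
        "974", "975", "976", "978", "979"]
    C: ["E8588", "E8589", "E9804", "E9805"]
  adverse_effect_therapeutic:
    # adverse effect of drug in therapeutic use (E930-E949)
    A: ["E9350", "E9351", "E9352", "E9359"]   # heroin/methadone/other opiates,
                                              # unspecified analgesic
    B: ["E9353", "E9354", "E9355", "E9356", "E9357", "E9358",
        "E930", "E931", "E932", "E933", "E934", "E936", "E937",
        "E938", "E939", "E940", "E941", "E942", "E943", "E944",
        "E945", "E946"]
    C: ["E9478", "E9479"]             # other / unspecified drug
  symptom_cns:
    # alteration of consciousness, altered mental status; deliberately
    # narrow (no dizziness-type codes)
    dx: ["7800", "78097"]
  symptom_respiratory:
    # respiratory failure/insufficiency/arrest, apnea
    dx: ["51881", "51882", "7991", "78603"]
exclusions:
  serious_illness:
    # malignant neoplasms and leukemias (140-209), sickle cell (282.6),
    # congenital anomalies (740-759)
    ["14", "15", "16", "17", "18", "19", "20", "2826", "74", "75"]
  transplant:
    ["V42"]
  institutional_residence:
    ["V606"]
  drug_abuse:
    ["304", "3055"]
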