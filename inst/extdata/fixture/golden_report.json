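{
  "sample_id": "SIMFIX",
  "parameters": {
    "overlap_key": "nt+vj",
    "min_alt_reads": 1,
    "k_max": 6,
    "n_restarts": 3,
    "seed": 11,
    "epsilon": 0.05,
    "eps_presence": 0.05,
    "j_max": 0.2,
    "s_min": 0.8,
    "subset_tol": 0.1
  },
  "clonotypes": {
    "n_neoplastic": {
      "epidermis": 3,
      "dermis": 3,
      "blood": 1
    },
    "tcf": {
      "epidermis": 0.85,
      "dermis": 0.55,
      "blood": 0.2
    },
    "overlap": {
      "n_shared": 1,
      "jaccard": 0.2,
      "n_a": 3,
      "n_b": 3
    },
    "shared": "GTAAATCAATGCCACCGACACATCCCGGAAACCTTC|TRBV5-1|TRBJ1-2",
    "venn": {
      "epi_only": 2,
      "derm_only": 2,
      "blood_only": 1,
      "epi_derm": 1,
      "epi_blood": 0,
      "derm_blood": 0,
      "all_three": 0,
      "union_size": 6
    }
  },
  "mutations": {
    "n_nonsynonymous": {
      "epidermis": 17,
      "dermis": 32
    },
    "overlap": {
      "n_epi_only": 15,
      "n_derm_only": 35,
      "n_shared": 8,
      "percent_overlap": 13.7931034482759
    },
    "driver_counts": {
      "both": 0,
      "epi_only": 0,
      "derm_only": 1
    },
    "driver_matrix": [
      {
        "gene": "NCOR1",
        "epidermis": "absent",
        "dermis": "missense",
        "_row": "NCOR1"
      },
      {
        "gene": "ARHGEF3",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "ARHGEF3"
      },
      {
        "gene": "ZEB1",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "ZEB1"
      },
      {
        "gene": "TP53",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "TP53"
      },
      {
        "gene": "PLCG1",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "PLCG1"
      },
      {
        "gene": "RFXAP",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "RFXAP"
      },
      {
        "gene": "CD58",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "CD58"
      },
      {
        "gene": "TNFRSF1B",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "TNFRSF1B"
      },
      {
        "gene": "JAK3",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "JAK3"
      },
      {
        "gene": "MAPK1",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "MAPK1"
      },
      {
        "gene": "PRKCB",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "PRKCB"
      },
      {
        "gene": "MTOR",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "MTOR"
      },
      {
        "gene": "NF1",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "NF1"
      },
      {
        "gene": "DNMT3A",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "DNMT3A"
      },
      {
        "gene": "TET2",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "TET2"
      },
      {
        "gene": "SMARCB1",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "SMARCB1"
      },
      {
        "gene": "KDM6A",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "KDM6A"
      },
      {
        "gene": "SETDB2",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "SETDB2"
      },
      {
        "gene": "STAT3",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "STAT3"
      },
      {
        "gene": "NFKB2",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "NFKB2"
      },
      {
        "gene": "NOTCH2",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "NOTCH2"
      },
      {
        "gene": "CARD11",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "CARD11"
      },
      {
        "gene": "STAT5B",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "STAT5B"
      },
      {
        "gene": "CDK12",
        "epidermis": "absent",
        "dermis": "absent",
        "_row": "CDK12"
      }
    ]
  },
  "phylogeny": {
    "n_subclones": 6,
    "n_subclones_epidermis": 3,
    "n_subclones_dermis": 3,
    "prevalence": [
      {
        "epidermis": 1,
        "dermis": 0.92,
        "_row": "c1"
      },
      {
        "epidermis": 0.9651,
        "dermis": 0,
        "_row": "c2"
      },
      {
        "epidermis": 0,
        "dermis": 0.9581,
        "_row": "c3"
      },
      {
        "epidermis": 0,
        "dermis": 0.3988,
        "_row": "c4"
      },
      {
        "epidermis": 0.3381,
        "dermis": 0,
        "_row": "c5"
      },
      {
        "epidermis": 0.014,
        "dermis": 0.0137,
        "_row": "c6"
      }
    ],
    "feasible": true,
    "stem_fraction": 0.131147540983607,
    "clade_fraction": 0.868852459016393,
    "stem_fraction_epidermis": 1,
    "stem_fraction_dermis": 1,
    "separation_score": 1,
    "common_ancestor_present": true,
    "newick": "(((c6_m8_epidermis=0.014|dermis=0.014)c5_m8_epidermis=0.338|dermis=0.000)c2_m4_epidermis=0.965|dermis=0.000,(c4_m16_epidermis=0.000|dermis=0.399)c3_m17_epidermis=0.000|dermis=0.958)c1_m8_epidermis=1.000|dermis=0.920;"
  },
  "verdict": {
    "verdict": "independent",
    "evidence": {
      "jaccard": 0.2,
      "separation_score": 1,
      "common_ancestor_present": true,
      "n_epi": 3,
      "n_derm": 3,
      "n_epi_outside_derm": 2,
      "subset_pattern": false,
      "thresholds": {
        "j_max": 0.2,
        "s_min": 0.8,
        "subset_tol": 0.1
      }
    }
  }
}
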