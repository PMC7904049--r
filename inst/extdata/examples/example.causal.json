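{
  "format_version": "1.0",
  "statements": [
    {
      "source": {
        "id": "uniprot:Q9WUA6",
        "label": "FOXO3_MOUSE",
        "modifications": [
          {
            "term": {
              "id": "MOD:00599",
              "label": "monomethylated residue"
            },
            "residue": {
              "id": "CHEBI:18019",
              "label": "L-lysine"
            },
            "position": 355
          }
        ]
      },
      "target": {
        "id": "uniprot:Q9WUA6",
        "label": "FOXO3_MOUSE"
      },
      "relation": {
        "id": "MI:2240",
        "label": "down-regulates"
      },
      "references": [
        {
          "id": "pubmed:14874920"
        },
        {
          "id": "pubmed:84417919"
        }
      ],
      "evidence": [
        {
          "id": "ECO:0000250",
          "label": "sequence similarity evidence used in manual assertion"
        }
      ],
      "mechanism": {
        "id": "MI:0220",
        "label": "ubiquitination reaction"
      },
      "taxon": {
        "id": "NCBITaxon:9606",
        "label": "Homo sapiens"
      }
    },
    {
      "source": {
        "id": "uniprot:P06493",
        "label": "CDK1_HUMAN"
      },
      "target": {
        "id": "uniprot:P06493",
        "label": "CDK1_HUMAN"
      },
      "relation": {
        "id": "RO:0002304",
        "label": "causally upstream of, positive effect"
      },
      "references": [
        {
          "id": "pubmed:57583406"
        }
      ],
      "evidence": [
        {
          "id": "ECO:0007682",
          "label": "reporter gene assay evidence used in manual assertion"
        }
      ]
    },
    {
      "source": {
        "id": "uniprot:P31750",
        "label": "AKT1_MOUSE",
        "modifications": [
          {
            "term": {
              "id": "MOD:00599",
              "label": "monomethylated residue"
            },
            "residue": {
              "id": "CHEBI:16857",
              "label": "L-threonine"
            },
            "position": 100
          }
        ]
      },
      "target": {
        "id": "uniprot:P31749",
        "label": "AKT1_HUMAN"
      },
      "relation": {
        "id": "RO:0002305",
        "label": "causally upstream of, negative effect"
      },
      "references": [
        {
          "id": "pubmed:27602326"
        },
        {
          "id": "pubmed:95035639"
        }
      ],
      "evidence": [
        {
          "id": "ECO:0000269",
          "label": "experimental evidence used in manual assertion"
        }
      ],
      "mechanism": {
        "id": "MI:0217",
        "label": "phosphorylation reaction"
      },
      "taxon": {
        "id": "NCBITaxon:10090",
        "label": "Mus musculus"
      }
    }
  ]
}
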