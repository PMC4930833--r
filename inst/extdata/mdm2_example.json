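{
  "id": "DOC-MDM2",
  "text": "mdm2 directly binds to the amino-terminal region of p53 and targets it for degradation through the ubiquitin-proteasome pathway",
  "sentences": [
    {
      "id": "SEN:000101",
      "start": 0,
      "end": 127,
      "tokens": [
        {
          "start": 0,
          "end": 4,
          "number": "singular",
          "pronoun": false,
          "definite": false,
          "pos": "NOUN"
        },
        {
          "start": 5,
          "end": 13,
          "number": "unknown",
          "pronoun": false,
          "definite": false,
          "pos": "ADV"
        },
        {
          "start": 14,
          "end": 19,
          "number": "unknown",
          "pronoun": false,
          "definite": false,
          "pos": "VERB"
        },
        {
          "start": 20,
          "end": 22,
          "number": "unknown",
          "pronoun": false,
          "definite": false,
          "pos": "ADP"
        },
        {
          "start": 23,
          "end": 26,
          "number": "unknown",
          "pronoun": false,
          "definite": true,
          "pos": "DET"
        },
        {
          "start": 27,
          "end": 41,
          "number": "unknown",
          "pronoun": false,
          "definite": false,
          "pos": "ADJ"
        },
        {
          "start": 42,
          "end": 48,
          "number": "unknown",
          "pronoun": false,
          "definite": false,
          "pos": "NOUN"
        },
        {
          "start": 49,
          "end": 51,
          "number": "unknown",
          "pronoun": false,
          "definite": false,
          "pos": "ADP"
        },
        {
          "start": 52,
          "end": 55,
          "number": "singular",
          "pronoun": false,
          "definite": false,
          "pos": "NOUN"
        },
        {
          "start": 56,
          "end": 59,
          "number": "unknown",
          "pronoun": false,
          "definite": false,
          "pos": "CONJ"
        },
        {
          "start": 60,
          "end": 67,
          "number": "unknown",
          "pronoun": false,
          "definite": false,
          "pos": "VERB"
        },
        {
          "start": 68,
          "end": 70,
          "number": "unknown",
          "pronoun": true,
          "definite": false,
          "pos": "PRON"
        },
        {
          "start": 71,
          "end": 74,
          "number": "unknown",
          "pronoun": false,
          "definite": false,
          "pos": "ADP"
        },
        {
          "start": 75,
          "end": 86,
          "number": "unknown",
          "pronoun": false,
          "definite": false,
          "pos": "NOUN"
        },
        {
          "start": 87,
          "end": 94,
          "number": "unknown",
          "pronoun": false,
          "definite": false,
          "pos": "ADP"
        },
        {
          "start": 95,
          "end": 98,
          "number": "unknown",
          "pronoun": false,
          "definite": true,
          "pos": "DET"
        },
        {
          "start": 99,
          "end": 119,
          "number": "unknown",
          "pronoun": false,
          "definite": false,
          "pos": "ADJ"
        },
        {
          "start": 120,
          "end": 127,
          "number": "unknown",
          "pronoun": false,
          "definite": false,
          "pos": "NOUN"
        }
      ],
      "noun_phrases": [
        {
          "start": 0,
          "end": 4,
          "head": 1,
          "number": "singular",
          "definite": false
        },
        {
          "start": 23,
          "end": 48,
          "head": 7,
          "number": "singular",
          "definite": true
        },
        {
          "start": 52,
          "end": 55,
          "head": 9,
          "number": "singular",
          "definite": false
        }
      ],
      "mentions": [
        {
          "start": 0,
          "end": 4,
          "category": "gene_or_protein"
        },
        {
          "start": 52,
          "end": 55,
          "category": "gene_or_protein"
        }
      ]
    }
  ]
}
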