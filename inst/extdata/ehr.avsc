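{
  "type": "record",
  "name": "EHRRecord",
  "fields": [
    {
      "name": "base",
      "type": {
        "type": "record",
        "name": "base_rec",
        "fields": [
          {
            "name": "age",
            "type": "int"
          },
          {
            "name": "gender",
            "type": "string"
          },
          {
            "name": "height",
            "type": {
              "type": "int",
              "qrstab.decimal": 1
            }
          },
          {
            "name": "weight",
            "type": {
              "type": "int",
              "qrstab.decimal": 1
            }
          },
          {
            "name": "bmi",
            "type": {
              "type": "int",
              "qrstab.decimal": 1
            }
          },
          {
            "name": "department",
            "type": {
              "type": "string",
              "qrstab.tokenized": true
            }
          },
          {
            "name": "hospitalDays",
            "type": "int"
          },
          {
            "name": "admissionDate",
            "type": {
              "type": "int",
              "qrstab.date": true
            }
          },
          {
            "name": "dischargeDate",
            "type": {
              "type": "int",
              "qrstab.date": true
            }
          },
          {
            "name": "admissionType",
            "type": "string"
          }
        ]
      }
    },
    {
      "name": "operate",
      "type": {
        "type": "array",
        "items": {
          "type": "record",
          "name": "operate_item",
          "fields": [
            {
              "name": "surgeryName",
              "type": {
                "type": "string",
                "qrstab.tokenized": true
              }
            },
            {
              "name": "surgeryDate",
              "type": {
                "type": "int",
                "qrstab.date": true
              }
            }
          ]
        }
      }
    },
    {
      "name": "image",
      "type": {
        "type": "array",
        "items": {
          "type": "record",
          "name": "image_item",
          "fields": [
            {
              "name": "examDate",
              "type": {
                "type": "int",
                "qrstab.date": true
              }
            },
            {
              "name": "examName",
              "type": {
                "type": "string",
                "qrstab.tokenized": true
              }
            },
            {
              "name": "bodyPart",
              "type": {
                "type": "string",
                "qrstab.tokenized": true
              }
            },
            {
              "name": "conclusion",
              "type": {
                "type": "string",
                "qrstab.tokenized": true
              }
            }
          ]
        }
      }
    },
    {
      "name": "lab",
      "type": {
        "type": "array",
        "items": {
          "type": "record",
          "name": "lab_item",
          "fields": [
            {
              "name": "indicatorName",
              "type": {
                "type": "string",
                "qrstab.tokenized": true
              }
            },
            {
              "name": "value",
              "type": {
                "type": "int",
                "qrstab.decimal": 2
              }
            },
            {
              "name": "unit",
              "type": {
                "type": "string",
                "qrstab.tokenized": true
              }
            },
            {
              "name": "riskFlag",
              "type": "string"
            },
            {
              "name": "normalRange",
              "type": {
                "type": "string",
                "qrstab.tokenized": true
              }
            }
          ]
        }
      }
    },
    {
      "name": "ass",
      "type": {
        "type": "array",
        "items": {
          "type": "record",
          "name": "ass_item",
          "fields": [
            {
              "name": "scaleName",
              "type": {
                "type": "string",
                "qrstab.tokenized": true
              }
            },
            {
              "name": "riskLevel",
              "type": "string"
            },
            {
              "name": "riskFactors",
              "type": {
                "type": "string",
                "qrstab.tokenized": true
              }
            }
          ]
        }
      }
    },
    {
      "name": "disease",
      "type": {
        "type": "array",
        "items": {
          "type": "record",
          "name": "disease_item",
          "fields": [
            {
              "name": "diseaseName",
              "type": {
                "type": "string",
                "qrstab.tokenized": true
              }
            },
            {
              "name": "category",
              "type": {
                "type": "string",
                "qrstab.tokenized": true
              }
            }
          ]
        }
      }
    },
    {
      "name": "drug",
      "type": {
        "type": "array",
        "items": {
          "type": "record",
          "name": "drug_item",
          "fields": [
            {
              "name": "drugName",
              "type": {
                "type": "string",
                "qrstab.tokenized": true
              }
            },
            {
              "name": "dailyDose",
              "type": {
                "type": "int",
                "qrstab.decimal": 2
              }
            },
            {
              "name": "frequency",
              "type": {
                "type": "string",
                "qrstab.tokenized": true
              }
            }
          ]
        }
      }
    }
  ]
}
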