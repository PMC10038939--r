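{
  "name": "AQUA-12",
  "version": "2",
  "total_max": 12,
  "elements": [
    {
      "element_id": "prev_adr_history",
      "name": "Previous ADR history",
      "allowed_scores": [0, 1, 2],
      "max_score": 2
    },
    {
      "element_id": "actual_reaction",
      "name": "Actual reaction",
      "allowed_scores": [0, 1, 2],
      "max_score": 2
    },
    {
      "element_id": "key_events",
      "name": "Description of key events",
      "allowed_scores": [0, 1, 2],
      "max_score": 2
    },
    {
      "element_id": "suspected_medications",
      "name": "Suspected medications",
      "allowed_scores": [0, 1, 2],
      "max_score": 2
    },
    {
      "element_id": "timeline",
      "name": "Timeline relevant to the nature of ADR",
      "allowed_scores": [0, 1],
      "max_score": 1
    },
    {
      "element_id": "management",
      "name": "Management of reaction",
      "allowed_scores": [0, 1],
      "max_score": 1
    },
    {
      "element_id": "outcome_sequelae",
      "name": "Outcome/sequelae",
      "allowed_scores": [0, 1, 2],
      "max_score": 2
    }
  ]
}
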