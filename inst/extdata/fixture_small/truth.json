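{
  "de_probes": {
    "probe": ["P0001", "P0001", "P0002", "P0002", "P0003", "P0003", "P0004", "P0004", "P0005", "P0005", "P0006", "P0006", "P0007", "P0007", "P0008", "P0008", "P0009", "P0009", "P0010", "P0010", "P0011", "P0011", "P0012", "P0012", "P0013", "P0013", "P0014", "P0014", "P0015", "P0015", "P0016", "P0016", "P0017", "P0017", "P0018", "P0018", "P0019", "P0019", "P0020", "P0020"],
    "state": ["MCI", "AD", "MCI", "AD", "MCI", "AD", "MCI", "AD", "MCI", "AD", "MCI", "AD", "MCI", "AD", "MCI", "AD", "MCI", "AD", "MCI", "AD", "MCI", "AD", "MCI", "AD", "MCI", "AD", "MCI", "AD", "MCI", "AD", "MCI", "AD", "MCI", "AD", "MCI", "AD", "MCI", "AD", "MCI", "AD"],
    "shift": [0.56, 0.8, -0.658, -0.94, 0.756, 1.08, -0.854, -1.22, 0.952, 1.36, -1.05, -1.5, 0.56, 0.8, -0.658, -0.94, 0.756, 1.08, -0.854, -1.22, 0.952, 1.36, -1.05, -1.5, 0.56, 0.8, -0.658, -0.94, 0.756, 1.08, -0.854, -1.22, 0.952, 1.36, -1.05, -1.5, 0.56, 0.8, -0.658, -0.94],
    "direction": ["Up", "Up", "Down", "Down", "Up", "Up", "Down", "Down", "Up", "Up", "Down", "Down", "Up", "Up", "Down", "Down", "Up", "Up", "Down", "Down", "Up", "Up", "Down", "Down", "Up", "Up", "Down", "Down", "Up", "Up", "Down", "Down", "Up", "Up", "Down", "Down", "Up", "Up", "Down", "Down"]
  },
  "edges_by_state": {
    "NC": {
      "source": ["P0001", "P0001", "P0001", "P0001", "P0001", "P0002", "P0002", "P0002", "P0002", "P0003", "P0003", "P0003", "P0004", "P0004", "P0005"],
      "target": ["P0002", "P0003", "P0004", "P0005", "P0006", "P0003", "P0004", "P0005", "P0006", "P0004", "P0005", "P0006", "P0005", "P0006", "P0006"],
      "r": [0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8]
    },
    "MCI": {
      "source": ["P0001", "P0001", "P0001", "P0001", "P0001", "P0002", "P0002", "P0002", "P0002", "P0003", "P0003", "P0003", "P0004", "P0004", "P0005", "P0007", "P0007", "P0007", "P0007", "P0007", "P0008", "P0008", "P0008", "P0008", "P0009", "P0009", "P0009", "P0010", "P0010", "P0011"],
      "target": ["P0002", "P0003", "P0004", "P0005", "P0006", "P0003", "P0004", "P0005", "P0006", "P0004", "P0005", "P0006", "P0005", "P0006", "P0006", "P0008", "P0009", "P0010", "P0011", "P0012", "P0009", "P0010", "P0011", "P0012", "P0010", "P0011", "P0012", "P0011", "P0012", "P0012"],
      "r": [0.8, 0.8, -0.8, -0.8, -0.8, 0.8, -0.8, -0.8, -0.8, -0.8, -0.8, -0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8]
    },
    "AD": {
      "source": ["P0001", "P0001", "P0001", "P0001", "P0001", "P0002", "P0002", "P0002", "P0002", "P0003", "P0003", "P0003", "P0004", "P0004", "P0005", "P0007", "P0007", "P0007", "P0007", "P0007", "P0008", "P0008", "P0008", "P0008", "P0009", "P0009", "P0009", "P0010", "P0010", "P0011"],
      "target": ["P0002", "P0003", "P0004", "P0005", "P0006", "P0003", "P0004", "P0005", "P0006", "P0004", "P0005", "P0006", "P0005", "P0006", "P0006", "P0008", "P0009", "P0010", "P0011", "P0012", "P0009", "P0010", "P0011", "P0012", "P0010", "P0011", "P0012", "P0011", "P0012", "P0012"],
      "r": [0.8, 0.8, -0.8, -0.8, -0.8, 0.8, -0.8, -0.8, -0.8, -0.8, -0.8, -0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8]
    }
  },
  "consensus_gained": {
    "source": ["P0007", "P0007", "P0007", "P0007", "P0007", "P0008", "P0008", "P0008", "P0008", "P0009", "P0009", "P0009", "P0010", "P0010", "P0011", "P0001", "P0001", "P0001", "P0002", "P0002", "P0002", "P0003", "P0003", "P0003"],
    "target": ["P0008", "P0009", "P0010", "P0011", "P0012", "P0009", "P0010", "P0011", "P0012", "P0010", "P0011", "P0012", "P0011", "P0012", "P0012", "P0004", "P0005", "P0006", "P0004", "P0005", "P0006", "P0004", "P0005", "P0006"],
    "sign": ["positive", "positive", "positive", "positive", "positive", "positive", "positive", "positive", "positive", "positive", "positive", "positive", "positive", "positive", "positive", "negative", "negative", "negative", "negative", "negative", "negative", "negative", "negative", "negative"]
  },
  "consensus_lost": {
    "source": ["P0001", "P0001", "P0001", "P0002", "P0002", "P0002", "P0003", "P0003", "P0003"],
    "target": ["P0004", "P0005", "P0006", "P0004", "P0005", "P0006", "P0004", "P0005", "P0006"],
    "sign": ["positive", "positive", "positive", "positive", "positive", "positive", "positive", "positive", "positive"]
  },
  "rewired_nodes": ["P0001", "P0002", "P0003", "P0004", "P0005", "P0006", "P0007", "P0008", "P0009", "P0010", "P0011", "P0012"]
}
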