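{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "regenworm worm-state document",
  "description": "Self-contained serialized worm state. All matrices are row-major nested arrays over the full cell lattice (rows x cols); coordinates are 1-based (row, col) with row 1 = dorsal edge and column 1 = anterior tip; dead or out-of-outline cells carry null voltages.",
  "type": "object",
  "required": ["schema_version", "config", "block_mask", "tissue_block",
               "node_block", "alive", "voltage", "status", "original_mask",
               "stems", "node_voltages"],
  "properties": {
    "schema_version": {"const": "1.0"},
    "config": {
      "type": "object",
      "description": "Worm configuration echo (geometry, voltages, thresholds, seed).",
      "required": ["block_size", "body_block_rows", "body_block_cols",
                   "taper", "node_blocks_body", "head_voltage",
                   "tail_voltage", "detect_threshold",
                   "border_depolarization", "stem_relay_cells", "seed"]
    },
    "block_mask": {"type": "array", "description": "Block-lattice occupancy (boolean matrix)."},
    "tissue_block": {"type": "array", "description": "Tissue name per block (head/body/tail/null)."},
    "node_block": {"type": "array", "description": "AMN node id (1..13) per block."},
    "alive": {"type": "array", "description": "Live somatic cells (boolean cell matrix)."},
    "voltage": {"type": "array", "description": "Normalized membrane voltage per cell; null when dead/absent."},
    "status": {"type": "array", "description": "Cell status: normal, affected, border, or null."},
    "original_mask": {"type": "array", "description": "Homeostatic occupancy (boolean cell matrix)."},
    "stems": {
      "type": "object",
      "description": "Stem-cell table (columns id, brow, bcol, row, col, voltage, alive, home_row, home_col)."
    },
    "node_voltages": {
      "type": "array", "items": {"type": "number"},
      "description": "Homeostatic attractor pattern, one strictly negative voltage per node, magnitude decreasing anterior to posterior."
    },
    "motifs": {
      "type": "object",
      "description": "Trained perceptron motifs (corner/border/interior), each with kind, k, w, b, trained, epochs, seed."
    },
    "amn": {
      "type": "object",
      "description": "Trained associative memory network: n, W (n x n weights), b, attractor, allow/sign topology masks, config, epochs, final_err."
    }
  }
}
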