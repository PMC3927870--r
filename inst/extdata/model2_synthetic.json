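{
  "schema_version": 1,
  "model_class": "protein_only",
  "genes": [
    {
      "id": "g1"
    },
    {
      "id": "g2"
    },
    {
      "id": "g3"
    },
    {
      "id": "g4"
    },
    {
      "id": "g5"
    },
    {
      "id": "g6",
      "operon": "o1"
    },
    {
      "id": "g7",
      "operon": "o1"
    },
    {
      "id": "g8"
    },
    {
      "id": "g9"
    },
    {
      "id": "g10"
    },
    {
      "id": "g11"
    }
  ],
  "regulations": [
    {
      "id": "r1",
      "source": "g1",
      "targets": [
        "g2"
      ],
      "sign": "repression"
    },
    {
      "id": "r2",
      "source": "g2",
      "targets": [
        "g3"
      ],
      "sign": "repression"
    },
    {
      "id": "r3",
      "source": "g3",
      "targets": [
        "g1"
      ],
      "sign": "repression"
    },
    {
      "id": "r4",
      "source": "g5",
      "targets": [
        "g4"
      ],
      "sign": "activation"
    },
    {
      "id": "r5",
      "source": "g4",
      "targets": [
        "g6",
        "g7"
      ],
      "sign": "activation"
    },
    {
      "id": "r6",
      "source": "g6",
      "targets": [
        "g8"
      ],
      "sign": "activation"
    },
    {
      "id": "r7",
      "source": "g7",
      "targets": [
        "g9"
      ],
      "sign": "repression"
    },
    {
      "id": "r8",
      "source": "g11",
      "targets": [
        "g10"
      ],
      "sign": "activation"
    },
    {
      "id": "r9",
      "source": "g8",
      "targets": [
        "g1"
      ],
      "sign": "repression"
    },
    {
      "id": "r10",
      "source": "g9",
      "targets": [
        "g2"
      ],
      "sign": "activation"
    },
    {
      "id": "r11",
      "source": "g10",
      "targets": [
        "g8"
      ],
      "sign": "repression"
    },
    {
      "id": "r12",
      "source": "g2",
      "targets": [
        "g6",
        "g7"
      ],
      "sign": "repression"
    },
    {
      "id": "r13",
      "source": "g11",
      "targets": [
        "g4"
      ],
      "sign": "repression"
    },
    {
      "id": "r14",
      "source": "g3",
      "targets": [
        "g10"
      ],
      "sign": "activation"
    },
    {
      "id": "r15",
      "source": "g5",
      "targets": [
        "g9"
      ],
      "sign": "activation"
    },
    {
      "id": "r16",
      "source": "g10",
      "targets": [
        "g3"
      ],
      "sign": "activation"
    }
  ],
  "parameters": {
    "r1_syn": 10,
    "r1_Kd": 1,
    "r1_h": 4,
    "r2_syn": 10,
    "r2_Kd": 1,
    "r2_h": 4,
    "r3_syn": 10,
    "r3_Kd": 1,
    "r3_h": 4,
    "r4_syn": 2,
    "r4_Kd": 1.5,
    "r4_h": 2,
    "r5_syn": 3,
    "r5_Kd": 2,
    "r5_h": 2,
    "r6_syn": 2.5,
    "r6_Kd": 1,
    "r6_h": 2,
    "r7_syn": 2,
    "r7_Kd": 2.5,
    "r7_h": 2,
    "r8_syn": 1.5,
    "r8_Kd": 1.2,
    "r8_h": 2,
    "r9_syn": 1,
    "r9_Kd": 3,
    "r9_h": 2,
    "r10_syn": 0.8,
    "r10_Kd": 1.5,
    "r10_h": 2,
    "r11_syn": 2,
    "r11_Kd": 2,
    "r11_h": 2,
    "r12_syn": 1.5,
    "r12_Kd": 1,
    "r12_h": 2,
    "r13_syn": 1,
    "r13_Kd": 2,
    "r13_h": 2,
    "r14_syn": 1.2,
    "r14_Kd": 1.5,
    "r14_h": 2,
    "r15_syn": 1.8,
    "r15_Kd": 1,
    "r15_h": 2,
    "r16_syn": 1.5,
    "r16_Kd": 2.5,
    "r16_h": 2,
    "g1_deg": 1,
    "g2_deg": 1,
    "g3_deg": 1,
    "g4_deg": 0.5,
    "g5_deg": 0.4,
    "g6_deg": 0.6,
    "g7_deg": 0.6,
    "g8_deg": 0.7,
    "g9_deg": 0.5,
    "g10_deg": 0.5,
    "g11_deg": 0.3,
    "g5_basal": 1,
    "g11_basal": 0.8
  },
  "initial_conditions": {
    "p_g1": 0,
    "p_g2": 0,
    "p_g3": 0,
    "p_g4": 0,
    "p_g5": 0,
    "p_g6": 0,
    "p_g7": 0,
    "p_g8": 0,
    "p_g9": 0,
    "p_g10": 0,
    "p_g11": 0
  }
}
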