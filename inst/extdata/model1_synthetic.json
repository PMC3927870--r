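{
  "schema_version": 1,
  "model_class": "mrna_protein",
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
      "id": "g6"
    },
    {
      "id": "g7"
    },
    {
      "id": "g8"
    },
    {
      "id": "g9"
    }
  ],
  "regulations": [
    {
      "id": "r1",
      "source": "g1",
      "targets": [
        "g2"
      ],
      "sign": "activation"
    },
    {
      "id": "r2",
      "source": "g2",
      "targets": [
        "g3"
      ],
      "sign": "activation"
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
      "source": "g1",
      "targets": [
        "g4"
      ],
      "sign": "activation"
    },
    {
      "id": "r5",
      "source": "g4",
      "targets": [
        "g5"
      ],
      "sign": "repression"
    },
    {
      "id": "r6",
      "source": "g6",
      "targets": [
        "g4"
      ],
      "sign": "repression"
    },
    {
      "id": "r7",
      "source": "g6",
      "targets": [
        "g7"
      ],
      "sign": "activation"
    },
    {
      "id": "r8",
      "source": "g7",
      "targets": [
        "g8"
      ],
      "sign": "activation"
    },
    {
      "id": "r9",
      "source": "g2",
      "targets": [
        "g5"
      ],
      "sign": "activation"
    },
    {
      "id": "r10",
      "source": "g5",
      "targets": [
        "g8"
      ],
      "sign": "repression"
    },
    {
      "id": "r11",
      "source": "g8",
      "targets": [
        "g9"
      ],
      "sign": "activation"
    },
    {
      "id": "r12",
      "source": "g9",
      "targets": [
        "g7"
      ],
      "sign": "repression"
    },
    {
      "id": "r13",
      "source": "g4",
      "targets": [
        "g3"
      ],
      "sign": "activation"
    }
  ],
  "parameters": {
    "g1_pro": 2,
    "g2_pro": 1.5,
    "g3_pro": 1.2,
    "g4_pro": 2.5,
    "g5_pro": 1.8,
    "g6_pro": 1,
    "g7_pro": 2.2,
    "g8_pro": 1.4,
    "g9_pro": 1.6,
    "g1_rbs": 1,
    "g2_rbs": 0.8,
    "g3_rbs": 1.5,
    "g4_rbs": 0.6,
    "g5_rbs": 1.2,
    "g6_rbs": 2,
    "g7_rbs": 0.9,
    "g8_rbs": 1.1,
    "g9_rbs": 0.7,
    "r1_Kd": 1,
    "r1_h": 2,
    "r2_Kd": 2,
    "r2_h": 2,
    "r3_Kd": 1.5,
    "r3_h": 3,
    "r4_Kd": 0.8,
    "r4_h": 2,
    "r5_Kd": 2.5,
    "r5_h": 2,
    "r6_Kd": 1.2,
    "r6_h": 1.5,
    "r7_Kd": 3,
    "r7_h": 2,
    "r8_Kd": 0.6,
    "r8_h": 2,
    "r9_Kd": 1,
    "r9_h": 2.5,
    "r10_Kd": 2,
    "r10_h": 1.5,
    "r11_Kd": 1.5,
    "r11_h": 2,
    "r12_Kd": 0.9,
    "r12_h": 3,
    "r13_Kd": 2.2,
    "r13_h": 2,
    "p_degradation_rate": 0.5
  },
  "initial_conditions": {
    "m_g1": 0,
    "m_g2": 0,
    "m_g3": 0,
    "m_g4": 0,
    "m_g5": 0,
    "m_g6": 0,
    "m_g7": 0,
    "m_g8": 0,
    "m_g9": 0,
    "p_g1": 0,
    "p_g2": 0,
    "p_g3": 0,
    "p_g4": 0,
    "p_g5": 0,
    "p_g6": 0,
    "p_g7": 0,
    "p_g8": 0,
    "p_g9": 0
  }
}
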