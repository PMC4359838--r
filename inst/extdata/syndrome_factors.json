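{
  "factors": {
    "qi_stagnation": {
      "latents": ["Y0", "Y1", "Y9"],
      "exclusions": ["chills", "dizziness"]
    },
    "dampness": {
      "latents": ["Y5", "Y9", "Y13"],
      "exclusions": []
    },
    "blood_stasis": {
      "latents": ["Y0", "Y2", "Y4", "Y7", "Y9"],
      "exclusions": ["slippery pulse", "plump tongue"]
    },
    "heat": {
      "latents": ["Y8", "Y12", "Y13"],
      "exclusions": []
    },
    "deficiency": {
      "latents": ["Y2", "Y3", "Y10", "Y11", "Y12"],
      "exclusions": [],
      "sub_exclusions": ["bitter taste"]
    }
  },
  "anchors": {
    "Y0": ["hypochondriac pain", "chest pain"],
    "Y1": ["stomach bloating", "chills", "chest distress", "stomachache", "dizziness", "abdominal distension", "shoulder and back pain", "depression"],
    "Y2": ["anorexia", "hypochondrium block", "nausea and vomiting"],
    "Y3": ["dim complexion", "night sweating", "loose stool", "tinnitus", "sallow complexion", "pale complexion", "spontaneous sweating"],
    "Y4": ["purplish tongue", "plump tongue", "sublingual vein varicose", "petechiae tongue"],
    "Y5": ["greasy tongue coating", "yellow tongue coating", "white tongue coating", "heavy head and body"],
    "Y6": ["red tongue"],
    "Y7": ["cyanotic lips and nails", "liver palms and spider nevus"],
    "Y8": ["fever", "hectic fever", "rapid pulse", "ascites", "pale lips and nails"],
    "Y9": ["taut pulse", "slippery pulse", "unsmooth pulse"],
    "Y10": ["thready pulse", "weak pulse"],
    "Y11": ["fatigue", "lumbar genu aching and limp", "insomnia", "night urination"],
    "Y12": ["dry mouth and throat", "bitter taste", "heat in palms and soles", "thirst", "dry stool"],
    "Y13": ["yellow urine", "hiccup", "jaundice", "edema in feet and legs", "bad breath", "hydrothorax", "oliguria"]
  }
}
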