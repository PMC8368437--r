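{
  "version": "1.0",
  "frame": "head frame, mm: origin = midpoint of preauricular points, x -> right preauricular, y -> nasion, z -> up; right-handed",
  "note": "Synthetic axis-aligned region boxes with anatomy-inspired extents for a ~96 mm modelling sphere. A voxel takes the label of the highest-priority (lowest number) box containing it; DBA is the catch-all.",
  "regions": [
    {"label": "MFC", "fullname": "medial frontal cortex", "priority": 1,
     "xmin": -22, "xmax": 22, "ymin": 20, "ymax": 96, "zmin": 8, "zmax": 75},
    {"label": "LFL", "fullname": "lateral frontal lobe (left)", "priority": 2,
     "xmin": -96, "xmax": -30, "ymin": 20, "ymax": 96, "zmin": -10, "zmax": 75},
    {"label": "LFL", "fullname": "lateral frontal lobe (right)", "priority": 3,
     "xmin": 30, "xmax": 96, "ymin": 20, "ymax": 96, "zmin": -10, "zmax": 75},
    {"label": "FC", "fullname": "frontal cortex (other)", "priority": 4,
     "xmin": -96, "xmax": 96, "ymin": 20, "ymax": 96, "zmin": -20, "zmax": 96},
    {"label": "TH", "fullname": "thalamus", "priority": 5,
     "xmin": -20, "xmax": 20, "ymin": -25, "ymax": 18, "zmin": -5, "zmax": 25},
    {"label": "PCC", "fullname": "posterior cingulate cortex", "priority": 6,
     "xmin": -18, "xmax": 18, "ymin": -60, "ymax": -18, "zmin": 18, "zmax": 45},
    {"label": "Pc", "fullname": "precuneus", "priority": 7,
     "xmin": -22, "xmax": 22, "ymin": -78, "ymax": -30, "zmin": 45, "zmax": 80},
    {"label": "TPJ", "fullname": "temporoparietal junction (left)", "priority": 8,
     "xmin": -96, "xmax": -28, "ymin": -65, "ymax": -15, "zmin": 10, "zmax": 45},
    {"label": "TPJ", "fullname": "temporoparietal junction (right)", "priority": 9,
     "xmin": 28, "xmax": 96, "ymin": -65, "ymax": -15, "zmin": 10, "zmax": 45},
    {"label": "TC", "fullname": "temporal cortex (left)", "priority": 10,
     "xmin": -96, "xmax": -28, "ymin": -30, "ymax": 20, "zmin": -40, "zmax": 15},
    {"label": "TC", "fullname": "temporal cortex (right)", "priority": 11,
     "xmin": 28, "xmax": 96, "ymin": -30, "ymax": 20, "zmin": -40, "zmax": 15},
    {"label": "MOC", "fullname": "medial occipital cortex", "priority": 12,
     "xmin": -25, "xmax": 25, "ymin": -96, "ymax": -52, "zmin": -15, "zmax": 35},
    {"label": "CE", "fullname": "cerebellum", "priority": 13,
     "xmin": -45, "xmax": 45, "ymin": -96, "ymax": -30, "zmin": -96, "zmax": -18},
    {"label": "POT", "fullname": "parieto-occipito-temporal", "priority": 14,
     "xmin": -96, "xmax": 96, "ymin": -96, "ymax": -35, "zmin": -40, "zmax": 50},
    {"label": "PL", "fullname": "parietal lobe", "priority": 15,
     "xmin": -96, "xmax": 96, "ymin": -55, "ymax": 20, "zmin": 25, "zmax": 96},
    {"label": "DBA", "fullname": "deep brain areas", "priority": 16,
     "xmin": -1000, "xmax": 1000, "ymin": -1000, "ymax": 1000, "zmin": -1000, "zmax": 1000}
  ]
}
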