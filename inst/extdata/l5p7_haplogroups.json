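{
  "name": "L5'7 haplogroup system",
  "reference": "synthetic-rCRS-like",
  "nodes": [
    {"name": "L2'3'4'5'6'7", "parent": null, "variants": []},
    {"name": "L5'7", "parent": "L2'3'4'5'6'7",
     "variants": ["T3423C", "C12432T", "A16166G"]},
    {"name": "L7", "parent": "L5'7",
     "variants": ["A6527G", "T11809C"]},
    {"name": "L7a", "parent": "L7",
     "variants": ["G3918A", "G4092A", "A7765G", "A15236G"]},
    {"name": "L7a*", "parent": "L7a",
     "variants": ["T146C!", "C198T", "A550G", "A3334G", "T3345C", "T4679C",
                  "C6164T", "G6260A", "T8450C", "G8485A", "G9947A", "G10775A",
                  "C10920T", "A11023G", "A11734G", "A12021c", "C12669T",
                  "T12892C", "T13581C", "T14020C", "A14548G", "G15301A",
                  "A15924G", "T15941C", "G16042A", "G16145A", "T16362C"]},
    {"name": "L7a1", "parent": "L7a",
     "variants": ["T182C!", "(573.XC)", "T1717C", "G1719A", "T2080C", "C2484T",
                  "A3564G", "G4655A", "C4676T", "T4967C", "G7789A", "T9018C",
                  "T9653C", "T10101C", "C11266T", "T11287C", "A12507G",
                  "G12940A", "A13050G", "C13383T", "T13602C", "C15418T",
                  "C16189T", "A16254G", "C16311T", "T16368C", "C16527T"]},
    {"name": "L7b", "parent": "L7",
     "variants": ["G3592A", "G3705A", "C5530T", "T7389C", "T7711C", "G8152A",
                  "G9755A", "C12178T", "G12651c", "T16209C", "G16213A"]},
    {"name": "L7b1", "parent": "L7b",
     "variants": ["T3027C", "G3316A", "A4871G", "T6216C", "T6620C", "G8027A",
                  "G8581A", "A9072G", "C9320T", "C9449T", "T10084C", "T10275C",
                  "T15514C", "C16256T"]},
    {"name": "L7b2", "parent": "L7b",
     "variants": ["T593C", "C3204T", "8281-8289d", "T8634C", "C8830T",
                  "C8992T", "G15927A", "T16172C"]},
    {"name": "L5", "parent": "L5'7",
     "variants": ["459.1C", "A7972G", "A12950G", "C16148T"]},
    {"name": "L5a", "parent": "L5",
     "variants": ["455.1T", "G709A", "A851G", "T1822C", "C5111T", "G5147A",
                  "A5656G", "G6182A", "T6297C", "A7424G", "G8155A", "A8188G",
                  "C8582T", "G9305A", "G9329A", "T11025C", "C11881T",
                  "G12236A", "A13105G!", "A13722G", "T14212C", "C14239T",
                  "T14581C", "G14905A", "T14971C", "G15217A", "G15884A",
                  "A16183c", "C16355T", "T16362C"]},
    {"name": "L5a1", "parent": "L5a",
     "variants": ["455.2T", "G930A", "C4496T", "C8754T"]},
    {"name": "L5a2", "parent": "L5a",
     "variants": ["C527T", "G8856A"]},
    {"name": "L5b", "parent": "L5",
     "variants": ["A3720G", "A9809c", "T10493C", "T11701C", "T12188C",
                  "A12546t", "T12714C", "A12810G", "T13569C", "T13830C",
                  "C16111T", "A16254G", "C16360T"]},
    {"name": "L5b1", "parent": "L5b",
     "variants": ["A249d", "C535T", "C2417g", "T3027C", "A4976G", "C5213T",
                  "C16311T"]},
    {"name": "L5b*", "parent": "L5b",
     "variants": ["C2380T", "T4233C", "A4529G", "T4907C", "C6173a", "C8829T",
                  "T8937C", "G9966A", "T10045C", "T11287C", "G12406A",
                  "A15442G"]}
  ]
}
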