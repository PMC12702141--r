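{
  "lacnac": "Gal(b1-4)GlcNAc",
  "lactose": "Gal(b1-4)Glc",
  "lac": "Gal(b1-4)Glc",
  "lacdinac": "GalNAc(b1-4)GlcNAc",
  "chitobiose": "GlcNAc(b1-4)GlcNAc",
  "maltose": "Glc(a1-4)Glc",
  "cellobiose": "Glc(b1-4)Glc",
  "melibiose": "Gal(a1-6)Glc",
  "gentiobiose": "Glc(b1-6)Glc",
  "lewisx": "Gal(b1-4)[Fuc(a1-3)]GlcNAc",
  "lex": "Gal(b1-4)[Fuc(a1-3)]GlcNAc",
  "lewisa": "Gal(b1-3)[Fuc(a1-4)]GlcNAc",
  "lea": "Gal(b1-3)[Fuc(a1-4)]GlcNAc",
  "sialyllewisx": "Neu5Ac(a2-3)Gal(b1-4)[Fuc(a1-3)]GlcNAc",
  "slex": "Neu5Ac(a2-3)Gal(b1-4)[Fuc(a1-3)]GlcNAc",
  "sialyllewisa": "Neu5Ac(a2-3)Gal(b1-3)[Fuc(a1-4)]GlcNAc",
  "slea": "Neu5Ac(a2-3)Gal(b1-3)[Fuc(a1-4)]GlcNAc",
  "2fl": "Fuc(a1-2)Gal(b1-4)Glc",
  "3fl": "Gal(b1-4)[Fuc(a1-3)]Glc",
  "3sl": "Neu5Ac(a2-3)Gal(b1-4)Glc",
  "6sl": "Neu5Ac(a2-6)Gal(b1-4)Glc",
  "lnt": "Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)Glc",
  "lnnt": "Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)Glc",
  "tantigen": "Gal(b1-3)GalNAc",
  "tn": "GalNAc",
  "tnantigen": "GalNAc",
  "core1": "Gal(b1-3)GalNAc",
  "core2": "Gal(b1-3)[GlcNAc(b1-6)]GalNAc",
  "core3": "GlcNAc(b1-3)GalNAc",
  "core4": "GlcNAc(b1-3)[GlcNAc(b1-6)]GalNAc",
  "bloodgroupa": "GalNAc(a1-3)[Fuc(a1-2)]Gal",
  "bloodgroupb": "Gal(a1-3)[Fuc(a1-2)]Gal",
  "bloodgrouph": "Fuc(a1-2)Gal",
  "gm3": "Neu5Ac(a2-3)Gal(b1-4)Glc",
  "gm2": "GalNAc(b1-4)[Neu5Ac(a2-3)]Gal(b1-4)Glc",
  "gm1": "Gal(b1-3)GalNAc(b1-4)[Neu5Ac(a2-3)]Gal(b1-4)Glc",
  "gd3": "Neu5Ac(a2-8)Neu5Ac(a2-3)Gal(b1-4)Glc",
  "gd1a": "Neu5Ac(a2-3)Gal(b1-3)GalNAc(b1-4)[Neu5Ac(a2-3)]Gal(b1-4)Glc",
  "lactotriaose": "GlcNAc(b1-3)Gal(b1-4)Glc",
  "isoglobotriose": "Gal(a1-3)Gal(b1-4)Glc",
  "globotriose": "Gal(a1-4)Gal(b1-4)Glc",
  "sialylt": "Neu5Ac(a2-3)Gal(b1-3)GalNAc",
  "polylacnac": "Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)GlcNAc"
}
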