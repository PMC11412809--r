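[
  {"id": "rgb_texture_1cm",  "source": "texture_rgb", "sensor": "rgb", "label": "1cm",  "equation": "LAI=15.448-0.179*Mea1-9.274*meacor1"},
  {"id": "rgb_texture_4cm",  "source": "texture_rgb", "sensor": "rgb", "label": "4cm",  "equation": "LAI=9.863-0.175*Mea4-12.465*homcor4"},
  {"id": "rgb_texture_8cm",  "source": "texture_rgb", "sensor": "rgb", "label": "8cm",  "equation": "LAI=51.659-45.959*meaent8-45.078*homcor8"},
  {"id": "rgb_texture_16cm", "source": "texture_rgb", "sensor": "rgb", "label": "16cm", "equation": "LAI=30.86-30.048*meacor16-64.9*seccor16"},
  {"id": "rgb_texture_24cm", "source": "texture_rgb", "sensor": "rgb", "label": "24cm", "equation": "LAI=29.268-28.6*meacor24-92.39*seccor24"},
  {"id": "rgb_texture_32cm", "source": "texture_rgb", "sensor": "rgb", "label": "32cm", "equation": "LAI=28.65-28.022*meacor32-119.2*seccor32"},
  {"id": "rgb_texture_40cm", "source": "texture_rgb", "sensor": "rgb", "label": "40cm", "equation": "LAI=4.148-30.288*meacor40 + 28.014*cor40"},
  {"id": "rgb_texture_48cm", "source": "texture_rgb", "sensor": "rgb", "label": "48cm", "equation": "LAI=-11.124-32.27*meacor48 + 44.35*Hom48"},
  {"id": "rgb_texture_all",  "source": "texture_rgb", "sensor": "rgb", "label": "All",  "equation": "LAI=-38.476 + 74.826*Hom40 + 0.621*Var4-29.84*seccor4-0.192*Var1-33.566*meahom1"},
  {"id": "mca_texture_8cm",  "source": "texture_mca", "sensor": "mca", "label": "8cm",  "equation": "LAI=5.935-6.795*meahom8-4.759*vardis8"},
  {"id": "mca_texture_16cm", "source": "texture_mca", "sensor": "mca", "label": "16cm", "equation": "LAI=7.879-7.626*meahom16"},
  {"id": "mca_texture_24cm", "source": "texture_mca", "sensor": "mca", "label": "24cm", "equation": "LAI=7.933-7.109*measec24"},
  {"id": "mca_texture_32cm", "source": "texture_mca", "sensor": "mca", "label": "32cm", "equation": "LAI=6.007-4.948*meacor32"},
  {"id": "mca_texture_40cm", "source": "texture_mca", "sensor": "mca", "label": "40cm", "equation": "LAI=5.759-4.722*meacor40"},
  {"id": "mca_texture_48cm", "source": "texture_mca", "sensor": "mca", "label": "48cm", "equation": "LAI=4.145-4.045*meacor48-1.746*discor48"},
  {"id": "mca_texture_all",  "source": "texture_mca", "sensor": "mca", "label": "All",  "equation": "LAI=5.568-5.823*measec24-2.108*discor48"},
  {"id": "fusion_rgb_si",          "source": "fusion", "sensor": "rgb", "label": "MSR-RGB SI",         "equation": "LAI=6.085-0.042B-5.82ExB"},
  {"id": "fusion_rgb_texture",     "source": "fusion", "sensor": "rgb", "label": "MSR-RGB Texture",    "equation": "LAI=-74.8Hom40 + 0.6Var4-29.84seccor4-0.19Var1-33.6meahom1 + 38.5"},
  {"id": "fusion_rgb_si_texture",  "source": "fusion", "sensor": "rgb", "label": "MSR-RGB SI+Texture", "equation": "LAI=-48.92-0.2Mea48 + 56.34Hom40 + 0.02G"},
  {"id": "fusion_mca_si",          "source": "fusion", "sensor": "mca", "label": "MSR-MCA SI",         "equation": "LAI=-0.209 + 32.94*R900-24.29*R800"},
  {"id": "fusion_mca_texture",     "source": "fusion", "sensor": "mca", "label": "MSR-MCA Texture",    "equation": "LAI=5.568-5.8measec24-2.11discor48"},
  {"id": "fusion_mca_si_texture",  "source": "fusion", "sensor": "mca", "label": "MSR-MCA SI+Texture", "equation": "LAI=-3.2meacor48 + 18.68R900-4.85VARI+2.2"}
]
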