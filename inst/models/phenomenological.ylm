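schema: 1
name: phenomenological
# Phenomenological single-cell model of dorsal follicle-cell fate choice.
# Three Boolean output fates (Roof, Floor, Operculum) read the EGF and BMP
# signalling inputs inside an anterior competence region; Roof_adj reports
# the presence of a differentiated roof cell among the direct neighbours
# (juxtacrine signal).
components:
  - {name: EGF, max: 2, input: true}
  - {name: BMP, max: 1, input: true}
  - {name: anterior, max: 1, input: true}
  - {name: Roof_adj, max: 1, input: true}
  - {name: Roof, max: 1}
  - {name: Floor, max: 1}
  - {name: Operculum, max: 1}
rules:
  Roof:
    - {if: "anterior & EGF=1 & !BMP", to: 1,
       note: "intermediate EGF within the competence region; repressed by high EGF and by BMP"}
  Operculum:
    - {if: "anterior & (EGF:2 | (EGF & BMP))", to: 1,
       note: "high EGF, or EGF together with BMP"}
  Floor:
    - {if: "anterior & (EGF:2 | (EGF & BMP)) & Roof_adj", to: 1,
       note: "operculum condition plus contact with a roof cell: floor lies on the operculum side of the roof border"}
priorities:
  - [Roof, Floor, Operculum]
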