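schema: 1
name: mechanistic
# Mechanistic single-cell network for dorsal eggshell patterning.
#
# Inputs: the late ligands Grk (graded, 4 levels) and Dpp (anterior band),
# the early posterior EGF and hypothesised early BMP signals that set the
# anterior competence region through Mid, and three extracellular variables
# filled by neighbour integration on the epithelium (Aos_ext, Rho_ext,
# Br_adj). Core internals: dpERK (EGF pathway activity, 3 levels), Mirr,
# Pnt, Rho (3 levels), Aos (delayed), Br (high-level, BrL-driven only).
#
# Derived integration nodes combine local and extracellular signals:
#   S combines local Rho with neighbour-released Spitz (Rho_ext),
#   A combines local Aos with paracrine Aos (local Aos alone is too weak:
#     it inhibits only together with extracellular Aos, while saturating
#     extracellular Aos inhibits on its own),
#   X is the juxtacrine roof signal: active in a non-roof cell (Br = 0)
#     touching at least one roof cell (Br_adj = 1).
#
# Free parameters not pinned down by published interactions (chiefly the
# dpERK activation table) are set so as to maximise the effect of X; the
# self-loops on Br and Mid stand for protein persistence, not
# autoregulation (flagged "maintenance").
components:
  - {name: early_EGF, max: 1, input: true}
  - {name: early_BMP, max: 1, input: true}
  - {name: Grk, max: 3, input: true}
  - {name: Dpp, max: 1, input: true}
  - {name: Aos_ext, max: 2, input: true}
  - {name: Rho_ext, max: 2, input: true}
  - {name: Br_adj, max: 1, input: true}
  - {name: Mid, max: 1}
  - {name: dpERK, max: 2}
  - {name: Mirr, max: 1}
  - {name: Pnt, max: 1}
  - {name: Rho, max: 2}
  - {name: Aos, max: 1, delay: 2}
  - {name: Br, max: 1, delay: 1}
derived:
  - name: S
    max: 2
    clauses:
      - {if: "Rho:2 | Rho_ext:2", to: 2, note: "high Spitz, released locally or by close neighbours"}
      - {if: "Rho | Rho_ext", to: 1}
  - name: A
    max: 1
    clauses:
      - {if: "Aos_ext:2 | (Aos & Aos_ext)", to: 1, note: "local Aos needs paracrine support; saturating paracrine Aos suffices"}
  - name: X
    max: 1
    clauses:
      - {if: "!Br & Br_adj", to: 1, note: "juxtacrine roof signal onto non-roof neighbours"}
rules:
  Mid:
    - {if: "early_EGF & !early_BMP", to: 1, note: "early posterior EGF induces Mid unless early BMP represses it"}
    - {if: "Mid", to: 1, note: "maintenance"}
  dpERK:
    - {if: "X & (Grk | Rho:2)", to: 2, note: "juxtacrine amplification: X drives peak activity wherever the cell receives Grk or already produces high Spitz (X effect maximised)"}
    - {if: "Grk:3", to: 2, note: "peak Grk drives full pathway activity regardless of Aos"}
    - {if: "S:2 & Mirr & !A", to: 2, note: "high Spitz sustains peak activity in cells already engaged in the EGF response (Mirr-positive), unless inhibited by Aos"}
    - {if: "Grk", to: 1, note: "sub-peak Grk gives low activity; Aos sequesters Spitz, not the Grk drive"}
  Mirr:
    - {if: "dpERK & !Mid", to: 1, note: "responds to low EGF activity; restricted to the competence region"}
  Pnt:
    - {if: "dpERK:2", to: 1, note: "requires high EGF activity"}
  Rho:
    - {if: "dpERK:2 & Mirr & !Br", to: 2, note: "EGF target via Mirr; repressed by Br"}
    - {if: "dpERK & Mirr & !Br", to: 1}
  Aos:
    - {if: "dpERK:2 & Pnt & !Mid", to: 1, note: "high EGF activity via Pnt; restricted to the competence region"}
  Br:
    - {if: "Mirr & !Pnt & !Dpp", to: 1, note: "BrL enhancer: Mirr activates, Pnt and Dpp repress"}
    - {if: "Br & !Pnt", to: 1, note: "maintenance"}
priorities:
  - [dpERK]
  - [Mid, Mirr, Pnt, Rho, Aos, Br]
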