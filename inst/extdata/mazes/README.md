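# Bundled maze fixtures

17 x 17 grids of 40 um cells (680 x 680 um). Glyphs: `#` barrier,
`.` corridor, `S` start, `E` egg. The first file line is the top row.

- `maze_A.txt` — open arena, no internal barriers; start top-left, egg
  bottom-right. Single-region convention: TC_w = 1.
- `maze_B_synthetic.txt` / `.json` — acyclic labyrinth, skeleton graph
  of 12 vertices and 11 edges, TC_w = 22.
- `maze_C_synthetic.txt` / `.json` — acyclic labyrinth, 28 vertices and
  27 edges, TC_w = 54; shortest start-to-egg path degree product
  3^7 * 4^2 = 34992.

Mazes B and C are synthetic reconstructions: labyrinths constructed to
satisfy the published graph statistics above (acyclicity, arena size,
egg placement, TC_w, path degree product), not copies of any published
drawing. The `.json` sidecars store the skeleton graphs
(`{"vertices": [{"id", "degree"}], "edges", "start", "egg"}`) and are
cross-checked against grid extraction by the test suite.
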