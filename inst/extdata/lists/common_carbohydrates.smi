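#matching: stereo_agnostic
# Common carbohydrates (rule R.5). Entries: SMILES<TAB>name.
OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O	D-glucose
OC[C@H]1OC(O)(CO)[C@@H](O)[C@@H]1O	D-fructose
OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@H]1O	D-galactose
OC[C@H]1OC(O)[C@H](O)[C@@H]1O	D-ribose
OCC1OC(O)C(O)C1O	D-xylose (pyranose drawn generic)
OC[C@H]1O[C@@](CO)(O[C@H]2O[C@H](CO)[C@@H](O)[C@H](O)[C@H]2O)[C@@H](O)[C@@H]1O	sucrose
OC[C@H]1O[C@@H](O[C@H]2[C@H](O)[C@@H](O)C(O)O[C@@H]2CO)[C@H](O)[C@@H](O)[C@H]1O	lactose
OC[C@H]1O[C@H](O[C@H]2[C@H](O)[C@@H](O)C(O)O[C@@H]2CO)[C@H](O)[C@@H](O)[C@@H]1O	maltose
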