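<?xml version="1.0" encoding="UTF-8"?>
<corpus>
  <annotation_unit id="u1">
    <pmid>20001</pmid>
    <sentence idx="0">EGFR is overexpressed in lung cancer</sentence>
    <gene start="1" end="4">EGFR</gene>
    <cancer_term start="26" end="36">lung cancer</cancer_term>
    <change>Gene_up-regulated</change>
  </annotation_unit>
  <annotation_unit id="u2">
    <pmid>20002</pmid>
    <sentence idx="1">PTEN expression was measured in glioma samples</sentence>
    <gene start="1" end="4">PTEN</gene>
    <cancer_term start="33" end="38">glioma</cancer_term>
    <change>none</change>
  </annotation_unit>
  <annotation_unit id="u3">
    <pmid>20003</pmid>
    <sentence idx="0">Loss of RB1 shows causality for retinoblastoma</sentence>
    <gene start="9" end="11">RB1</gene>
    <cancer_term start="33" end="46">retinoblastoma</cancer_term>
    <change>causality</change>
  </annotation_unit>
</corpus>
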