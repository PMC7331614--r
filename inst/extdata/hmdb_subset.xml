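<?xml version="1.0" encoding="UTF-8"?>
<hmdb>
  <metabolite>
    <accession>SMET00001</accession>
    <monisotopic_molecular_weight>175.0957</monisotopic_molecular_weight>
    <protein_associations>
      <protein><gene_name>GENEA</gene_name></protein>
      <protein><gene_name>GENEB</gene_name></protein>
    </protein_associations>
  </metabolite>
  <metabolite>
    <accession>SMET00002</accession>
    <monisotopic_molecular_weight>132.0535</monisotopic_molecular_weight>
    <protein_associations>
      <protein><gene_name>GENEA</gene_name></protein>
    </protein_associations>
  </metabolite>
  <metabolite>
    <accession>SMET00003</accession>
    <monoisotopic_mass>300.1250</monoisotopic_mass>
    <protein_associations>
      <protein><gene_name>GENEB</gene_name></protein>
    </protein_associations>
  </metabolite>
</hmdb>
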