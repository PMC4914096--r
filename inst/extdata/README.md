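# External data

`M13mp18_X02513.fa` (not redistributed): the M13mp18 single-stranded phage
genome, GenBank accession X02513, used as the low-repetitiveness baseline
(about 2% of its nucleotides sit in a 12-base window occurring more than
once). To enable the baseline check, fetch it once and place it here, e.g.:

    curl -o M13mp18_X02513.fa \
      'https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?db=nuccore&id=X02513&rettype=fasta&retmode=text'

Everything else in the package is generated programmatically by the fixture
module (`make_helix_bundle()`, `make_degenerate_cases()`).
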