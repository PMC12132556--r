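Package: ConformR
Title: Subsampled-Alignment Ensembles for Protein Conformational Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Tools for generating and analysing protein conformational
        ensembles obtained from stochastically subsampled multiple sequence
        alignments. Provides an A3M/FASTA alignment reader, a Hamming-distance
        cluster-centre subsampler controlled by the max_seq/extra_seq parameter
        pair, readers for ensembles of predicted structures carrying per-residue
        pLDDT in the B-factor field, Kabsch superposition and an iterative mean
        structure, a native TM-score, per-residue RMSF with peak calling,
        RMSD-versus-reference conformational-state clustering with population
        estimates, pairwise RMSD/TM-score matrices, a synthetic fixture
        generator with planted ground truth, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, grDevices, graphics, tools,
        Biostrings, bio3d, cluster, jsonlite, optparse, yaml
Suggests: testthat (>= 3.0.0)
biocViews: StructuralPrediction, MultipleSequenceAlignment, Clustering,
        Proteomics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ConformR-package.R'
    'cli.R'
    'ensemble-io.R'
    'fixtures.R'
    'flexibility.R'
    'geometry.R'
    'msa-io.R'
    'states.R'
    'subsample.R'
    'tm-score.R'
    'utils.R'
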