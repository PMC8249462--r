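Package: wolfped
Title: Genetic Monitoring of Recolonizing Wolf Populations
Version: 0.1.0
Authors@R:
    person("Conservation Genetics", "Toolkit", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for non-invasive genetic monitoring of territorial
    carnivore populations, built around the workflow used to reconstruct
    the recolonization of Germany by grey wolves: multiple-tube consensus
    microsatellite genotyping with allelic-dropout safeguards, individual
    identification, sex and mtDNA haplotype assignment, exclusion-based
    parentage with spatio-temporal constraints, pedigree kinship and
    inbreeding (tabular/Meuwissen-Luo recursion), allele-frequency
    diversity statistics (Na, Ne, Ho, He, rarefied allelic richness, PIC,
    PID/PIDsib), Hardy-Weinberg permutation tests, sex-biased dispersal
    tests (chi-square sex ratio, Wilcoxon rank-sum, mAIc permutation),
    Mann-Kendall/Sen trend analysis, exponential growth fits, core-area
    assignment with minimum convex polygons, and a recolonization
    simulator that provides ground truth for every pipeline stage. Ships
    the 2005-2015 German breeding-pair genealogy as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
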