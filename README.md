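# coordenum

Stereoisomer enumeration and 3D structure generation for mononuclear
coordination complexes.

## The problem

Quantum-chemical studies of transition-metal complexes start from 3D
coordinates, and for an octahedral or square-planar center those coordinates
are not unique: the same metal + ligand set can coordinate in many distinct
spatial arrangements. For six mutually distinguishable donor atoms on an
octahedron there are 6!/|O| = 720/24 = 30 rotation-distinct arrangements
(3 for four donors on a square plane), more when coordinated donor atoms
such as secondary amines become tetrahedral stereocenters, fewer when
ligands are repeated or symmetric. Choosing one arrangement by hand biases
every downstream energy comparison; `coordenum` enumerates all of them.

Ligands are written as SMILES in which each donor atom carries a nonzero
atom-map number, e.g. carbonyl `[C-:1]#[O+]`, ethylenediamine
`[NH2:1]CC[NH2:2]`, a thioether SNS pincer `C[S:1]CC[NH:2]CC[S:3]C`.
The package then:

1. places the donors on the polyhedron vertices in every possible way
   (720 or 24 raw placements);
2. expands donor atoms that become genuine tetrahedral stereocenters on
   coordination into both configurations (an isotope label 11/22 on a donor
   pins one configuration instead);
3. deduplicates through *canonical signature sets*: for each placement, one
   canonical molecular-graph string per symmetry operation of the polyhedron
   (24 rotations for OH, 8 permutations for SP); two stereoisomers are
   identical iff their sets intersect. Improper operations are added to the
   group when mirror-image pairs should merge (achiral environments);
4. optionally removes chemically infeasible arrangements: short-linker
   bidentate chelates spanning trans vertices, and rigid (terpyridine-like)
   tridentates bound facially — both rules can be switched off;
5. embeds each survivor in 3D by bounds-matrix distance geometry with
   metal-center constraints (metal–donor distance d from covalent radii;
   cis donor pairs at sqrt(2)·d, trans at 2·d), verifies that every
   donor–metal–donor angle classifies as intended, relaxes with a harmonic
   force field supplemented for dative bonds, re-verifies, and writes XYZ
   files whose comment line allows lossless reload.

Fixed-stereochemistry mode (map number = vertex index) skips the search and
also builds linear and square-pyramidal structures as octahedra with 2 or 5
defined donors.

## Worked example

```r
library(coordenum)

ligands <- generate_fixtures("monodentate")   # CO, H-, MeCN, Cl-, NH3, OH2
defn <- assemble_complex("Ru2+", "OH", as.list(ligands))
res  <- enumerate_stereomers(defn)
attr(res, "counts")
#>          raw     expanded deduplicated         kept
#>          720          720           30           30

res
#> # A tibble: 30 x 5
#>      id label        kept  removed_reason stereomer
#>   <int> <chr>        <lgl> <chr>          <list>
#> 1     1 unclassified TRUE  NA             <cdn_strm>
#> ...

confs <- embed(res$stereomer[[1]], n_conformers = 5, seed = 42)
length(confs)          # 5 verified conformers
confs[[1]]$energy      # force-field energy, comparative units
write_xyz(confs[[1]], "isomer_01.xyz")
read_xyz("isomer_01.xyz")$stereomer   # rebuilt, signature-equivalent
```

The 30 rows are the 30 rotation-distinct arrangements; with
`merge_enantiomers = TRUE` the count drops to 15 mirror-merged pairs. For a
pincer complex the `label` column reports the binding mode
(`fac`/`mer`/`bi`/`bic`), e.g.:

```r
xnx  <- generate_fixtures("tridentate_pincer_xnx")
defn <- assemble_complex("Ru2+", "OH", as.list(c(xnx, pincer_auxiliaries("Ru2+"))))
table(enumerate_stereomers(defn)$label)
#> fac mer
#>   6   9
```

(the secondary-amine central donor is a stereocenter after coordination,
which is why more than the 2 naive fac/mer placements survive).

## Command line

```sh
inst/cli/coordenum enumerate --metal Ru2+ --geometry OH \
    --ligands '[C-:1]#[O+],[H-:1],CC#[N:1],[Cl-:1],[NH3:1],[OH2:1]'
inst/cli/coordenum embed --config run.yaml --seed 7 --outdir out/
inst/cli/coordenum fixed --metal Ag+ --geometry OH --ligands '[C-:1]#[O+],[C-:6]#[O+]'
```

`enumerate` writes `stereomers.tsv` with labels and removal reasons; `embed`
writes one directory per stereoisomer containing `conf_XX.xyz`; stage counts
(raw → deduplicated → kept → embedded) are logged to stderr.

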