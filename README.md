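# DomainContacts

Residue- and atom-level interaction calling between protein-family
domains — and between domains and small-molecule ligands — in 3D
structures.

High-throughput interaction screens say *that* two proteins touch;
only high-resolution structures say *how*. Given a legacy-format PDB
coordinate file and a table of family-domain regions on its chains,
`DomainContacts` detects every inter-molecular atomic bond, classifies
it, and aggregates the bonds into domain–domain (DDI) and
domain–ligand (DLI) interaction calls with residue-level interface
detail. It is aimed at structural bioinformaticians building contact
databases or inspecting individual interfaces, and is equally usable
as an R library or from the shell.

## The bond model

For an atom pair at distance *d*, with covalent radii *r<sub>c</sub>*,
van der Waals radii *R*, formal charge signs *q* ∈ {−1, 0, +1} and
heavy-atom donor/acceptor flags, the classes are tried in precedence
order and the first match wins:

| class | rule |
|---|---|
| covalent | *d* < *r<sub>c</sub>(a)* + *r<sub>c</sub>(b)* |
| electrostatic | *r<sub>c</sub>(a)*+*r<sub>c</sub>(b)* < *d* < *R(a)*+*R(b)*, charges of opposite sign |
| hydrogen | neither above; donor + acceptor, *d* < 3.6 Å, acceptor angle ∈ [90°, 140°] |
| van der Waals | *R(a)*+*R(b)* < *d* < *R(a)*+*R(b)* + 1.5 Å |

One bond of any class suffices to call an interaction — deliberately no
minimum interface size. Van der Waals bonds, the overwhelming majority
at any interface, are stored as per-residue-pair flags rather than atom
pairs; covalent/electrostatic/hydrogen bonds are kept individually.
Domain annotations are cleaned first: regions on obsolete entries are
dropped, and overlapping matches on a chain are resolved greedily by
ascending E-value so only the most significant match survives.
HETATM residues become ligands unless they are solvents, nucleic-acid
components, MODRES-listed, or covalently LINKed to their own chain.
See `vignettes/domain-interactions.Rmd` for the full model, the
parameter table and every edge-case policy.

## Worked example

A Glu side-chain carboxylate oxygen placed 2.1 Å from a zinc ion (one
of the engineered fixtures shipped with the package):

```r
library(DomainContacts)
f <- fixtureSuite()$elec_dli_intra
res <- runPipeline(paste(f$pdb, collapse = "\n"),
                   paste(f$domains, collapse = "\n"), verbose = TRUE)
#> parsed 2 atoms on 1 chain(s)
#> 1 domain region(s) after overlap resolution
#> 1 domain instance(s), 1 ligand(s)
#> 1 interaction(s) called
res$interactions[[1]]
#> DLI PF00001 -- ZN [intramolecular]
#>   bonds: 0 covalent, 1 electrostatic, 0 hydrogen; 0 residue pairs with vdW flag
#>   1 residue contacts
res$summary
#>                homodomain heterodomain ligand
#> intramolecular          0            0      1
#> intermolecular          0            0      0
```

The O–Zn distance (2.1 Å) falls between the covalent-radius sum
(1.88 Å) and the van der Waals sum (3.53 Å) and the charges are −1/+1,
so the pair is an electrostatic bond; a single bond calls one
intramolecular DLI, which lands in exactly one cell of the summary
grid.

From the shell, the same pipeline writes four TSVs (`interactions`,
`bonds`, `residue_contacts`, `summary`):

```sh
Rscript inst/scripts/calc.R run --pdb structure.pdb \
    --domains domains.tsv --out results/ -v
```

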