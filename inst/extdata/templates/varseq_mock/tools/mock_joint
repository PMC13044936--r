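#!/bin/sh
# toy joint genotyper: merges per-sample gVCF tables into one cohort table
OUT=""; FILES=""
while [ $# -gt 0 ]; do
  case "$1" in
    -o) OUT="$2"; shift 2 ;;
    *) FILES="$FILES $1"; shift ;;
  esac
done
[ -n "$OUT" ] && [ -n "$FILES" ] || { echo "usage: mock_joint -o out gvcf..." >&2; exit 2; }
for f in $FILES; do
  [ -f "$f" ] || { echo "mock_joint: no such file: $f" >&2; exit 1; }
done
TAB=$(printf '\t')
{
  printf '#CHROM\tPOS\tGENE\tREF\tALT\tQUAL\tSAMPLE\n'
  grep -h -v '^#' $FILES | LC_ALL=C sort -t "$TAB" -k2,2n -k7,7
} > "$OUT"
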