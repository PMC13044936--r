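#!/bin/sh
# toy alignment statistics: alignment count and distinct positions
IN=""; OUT=""
while [ $# -gt 0 ]; do
  case "$1" in
    -i) IN="$2"; shift 2 ;;
    -o) OUT="$2"; shift 2 ;;
    *) shift ;;
  esac
done
[ -n "$IN" ] && [ -n "$OUT" ] || { echo "usage: mock_alnstats -i in -o out" >&2; exit 2; }
[ -f "$IN" ] || { echo "mock_alnstats: no such file: $IN" >&2; exit 1; }
n=$(wc -l < "$IN" | tr -d ' ')
p=$(cut -f3 "$IN" | LC_ALL=C sort -u | wc -l | tr -d ' ')
printf 'metric\tvalue\nalignments\t%s\npositions\t%s\n' "$n" "$p" > "$OUT"
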