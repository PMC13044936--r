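#!/usr/bin/env python
"""Independent oracle for tests.

Modes:
  cwl-oracle.py bind <tool.cwl> <job.yml>   print the argv, one token/line
  cwl-oracle.py dot <file.dot>              validate DOT grammar (exit 0/1)

The binding implementation follows the CWL v1.2 CommandLineTool argument
binding rules (position / prefix / separate / itemSeparator, boolean and
array handling), with ties on position broken by arguments (declaration
order) before inputs (lexicographic by id). It is written directly from
the standard and shares no code with the R implementation it checks.
"""
import sys
import yaml


def value_str(v):
    if isinstance(v, dict) and v.get("class") == "File":
        return str(v["path"])
    if isinstance(v, bool):
        return "true" if v else "false"
    return str(v)


def tokens(v, typ, prefix, sep, isep):
    if isinstance(v, bool) or typ == "boolean":
        if v is True or v == "true":
            return [prefix] if prefix is not None else []
        return []
    if isinstance(v, list):
        elems = [value_str(e) for e in v]
        if not elems:
            return []
        if isep is not None:
            j = isep.join(elems)
            if prefix is None:
                return [j]
            return [prefix, j] if sep else [prefix + j]
        if prefix is None:
            return elems
        if sep:
            out = []
            for e in elems:
                out += [prefix, e]
            return out
        return [prefix + e for e in elems]
    s = value_str(v)
    if prefix is None:
        return [s]
    return [prefix, s] if sep else [prefix + s]


def bind(tool_path, job_path):
    with open(tool_path) as fh:
        tool = yaml.safe_load(fh)
    with open(job_path) as fh:
        job = yaml.safe_load(fh) or {}
    assert tool.get("class") == "CommandLineTool"
    base = tool["baseCommand"]
    if isinstance(base, str):
        base = [base]
    argv = [str(b) for b in base]

    entries = []
    for i, a in enumerate(tool.get("arguments") or []):
        if isinstance(a, (str, int, float)):
            entries.append((0, 0, "%06d" % i, [str(a)]))
        else:
            toks = tokens(a.get("valueFrom"), "string", a.get("prefix"),
                          a.get("separate", True), None)
            if toks:
                entries.append((int(a.get("position", 0)), 0, "%06d" % i,
                                toks))

    inputs = tool.get("inputs") or {}
    if isinstance(inputs, list):
        inputs = {p["id"]: p for p in inputs}
    else:
        inputs = {k: (v if isinstance(v, dict) else {"type": v})
                  for k, v in inputs.items()}
    for iid in inputs:
        spec = inputs[iid]
        ib = spec.get("inputBinding")
        if ib is None:
            continue
        v = job.get(iid, spec.get("default"))
        if v is None:
            continue
        typ = spec.get("type", "string")
        if isinstance(typ, dict):
            typ = "%s[]" % typ.get("items", "string")
        toks = tokens(v, str(typ).rstrip("?"), ib.get("prefix"),
                      ib.get("separate", True), ib.get("itemSeparator"))
        if toks:
            entries.append((int(ib.get("position", 0)), 1, iid, toks))

    entries.sort(key=lambda e: (e[0], e[1], e[2]))
    for e in entries:
        argv.extend(e[3])
    sys.stdout.write("\n".join(argv) + "\n")


# --- minimal DOT grammar validator -------------------------------------

def dot_tokens(text):
    i, n = 0, len(text)
    while i < n:
        c = text[i]
        if c.isspace():
            i += 1
            continue
        if c == '"':
            j = i + 1
            while j < n:
                if text[j] == "\\":
                    j += 2
                    continue
                if text[j] == '"':
                    break
                j += 1
            if j >= n:
                raise SyntaxError("unterminated string")
            yield ("ID", text[i:j + 1])
            i = j + 1
            continue
        if text.startswith("->", i):
            yield ("EDGE", "->")
            i += 2
            continue
        if c in "{}[];=,":
            yield (c, c)
            i += 1
            continue
        j = i
        while j < n and (text[j].isalnum() or text[j] in "_.#"):
            j += 1
        if j == i:
            raise SyntaxError("unexpected character %r" % c)
        yield ("ID", text[i:j])
        i = j


def validate_dot(path):
    with open(path) as fh:
        toks = list(dot_tokens(fh.read()))
    pos = [0]

    def peek():
        return toks[pos[0]] if pos[0] < len(toks) else ("EOF", "")

    def eat(kind, val=None):
        t = peek()
        if t[0] != kind or (val is not None and t[1] != val):
            raise SyntaxError("expected %s %s, got %r" % (kind, val, t))
        pos[0] += 1
        return t

    def attr_list():
        eat("[")
        while peek()[0] != "]":
            eat("ID")
            eat("=")
            eat("ID")
            if peek()[0] == ",":
                eat(",")
        eat("]")

    t = eat("ID")
    if t[1] not in ("digraph", "graph"):
        raise SyntaxError("expected digraph")
    if peek()[0] == "ID":
        eat("ID")
    eat("{")
    while peek()[0] != "}":
        eat("ID")
        if peek()[0] == "=":          # graph attribute  a=b;
            eat("=")
            eat("ID")
        elif peek()[0] == "EDGE":     # edge stmt
            while peek()[0] == "EDGE":
                eat("EDGE")
                eat("ID")
            if peek()[0] == "[":
                attr_list()
        elif peek()[0] == "[":        # node stmt / node defaults
            attr_list()
        eat(";")
    eat("}")
    if peek()[0] != "EOF":
        raise SyntaxError("trailing content")


def main():
    mode = sys.argv[1]
    if mode == "bind":
        bind(sys.argv[2], sys.argv[3])
    elif mode == "dot":
        try:
            validate_dot(sys.argv[2])
        except SyntaxError as e:
            sys.stderr.write("invalid DOT: %s\n" % e)
            sys.exit(1)
    else:
        sys.exit(2)


if __name__ == "__main__":
    main()
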